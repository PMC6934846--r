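# Independent oracles and fixture builders shared across the suite.

# Greedy non-overlapping left-to-right substring count (plain R scan,
# independent of the C++ counter and of grammar counts).
greedy_count <- function(s, pat) {
  s <- as.character(unclass(s)); pat <- as.character(pat)
  n <- length(s); m <- length(pat)
  i <- 1L; cnt <- 0L
  while (i + m - 1L <= n) {
    if (all(s[i:(i + m - 1L)] == pat)) {
      cnt <- cnt + 1L
      i <- i + m
    } else i <- i + 1L
  }
  cnt
}

# Brute-force derivation oracle: rewrite S one non-terminal at a time,
# counting how often each rule is used (independent of the occurrence-count
# recurrence).
deriv_counts <- function(g) {
  cnt <- stats::setNames(rep(0L, length(g$rules)), names(g$rules))
  cnt["S"] <- 1L
  work <- g$rules[["S"]]
  repeat {
    nts <- which(startsWith(work, "#"))
    if (length(nts) == 0L) break
    i <- nts[1L]
    nm <- substring(work[i], 2L)
    cnt[nm] <- cnt[nm] + 1L
    work <- append(work[-i], g$rules[[nm]], after = i - 1L)
  }
  cnt
}

random_sequence <- function(alphabet_size, n) {
  as.character(sample(letters[seq_len(alphabet_size)], n, replace = TRUE))
}

# A small cohort for pipeline tests: short sessions keep the suite fast.
tiny_cohort <- function(n_per_class = 2L, session_s = 240,
                        strength = 0.8, seed = 7L) {
  generate_cohort(cohort_spec(n_per_class = n_per_class,
                              session_s = session_s,
                              repetition_strength = strength, seed = seed))
}

make_traj <- function(x, y, ...) trajectory(x, y, ...)

csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
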