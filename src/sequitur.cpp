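// Sequitur grammar induction (Nevill-Manning & Witten) plus a small
// non-overlapping substring counter used for motif frequencies.
//
// The grammar is built incrementally while maintaining two properties:
//   digram uniqueness - no pair of adjacent symbols occurs twice;
//   rule utility      - every rule other than S is referenced at least twice.
// Rule bodies are doubly linked symbol lists with a guard node; the digram
// index maps (symbol, symbol) keys to the first symbol of the occurrence.

#include <Rcpp.h>
#include <map>
#include <utility>
#include <vector>

namespace {

struct Rule;

struct Sym {
  long value = 0;        // terminal code (> 0) when rule == nullptr
  Rule *rule = nullptr;  // non-null for a non-terminal reference
  Sym *next = nullptr;
  Sym *prev = nullptr;
  bool guard = false;
  Rule *owner = nullptr;  // set on guard nodes only
};

struct Rule {
  Sym *guard = nullptr;
  int count = 0;  // number of references from rule bodies
  long id = 0;
  bool alive = true;
};

class Sequitur {
 public:
  typedef std::pair<long, long> Key;

  std::map<Key, Sym *> table;
  std::vector<Sym *> all_syms;
  std::vector<Rule *> all_rules;
  long next_rule_id = 0;

  ~Sequitur() {
    for (Sym *s : all_syms) delete s;
    for (Rule *r : all_rules) delete r;
  }

  Sym *new_terminal(long v) {
    Sym *s = new Sym();
    s->value = v;
    all_syms.push_back(s);
    return s;
  }

  Sym *new_nonterminal(Rule *r) {
    Sym *s = new Sym();
    s->rule = r;
    r->count++;
    all_syms.push_back(s);
    return s;
  }

  Rule *new_rule() {
    Rule *r = new Rule();
    r->id = next_rule_id++;
    Sym *g = new Sym();
    g->guard = true;
    g->owner = r;
    g->next = g;
    g->prev = g;
    r->guard = g;
    all_syms.push_back(g);
    all_rules.push_back(r);
    return r;
  }

  static long key_of(const Sym *s) {
    return s->rule ? -(s->rule->id) - 1 : s->value;
  }

  Key dkey(const Sym *s) const {
    return Key(key_of(s), key_of(s->next));
  }

  // Remove the index entry for the digram starting at s, if it points at s.
  void delete_digram(Sym *s) {
    if (s->guard || s->next == nullptr || s->next->guard) return;
    std::map<Key, Sym *>::iterator it = table.find(dkey(s));
    if (it != table.end() && it->second == s) table.erase(it);
  }

  void join(Sym *left, Sym *right) {
    if (left->next) {
      delete_digram(left);
      // Runs of equal symbols overlap their digrams and only one occurrence
      // is indexed; when relinking removes that one, re-index the
      // overlapping neighbour so the run stays visible to later checks.
      if (!right->guard && right->prev && right->next &&
          !right->prev->guard && !right->next->guard &&
          key_of(right) == key_of(right->prev) &&
          key_of(right) == key_of(right->next)) {
        table[dkey(right)] = right;
      }
      if (!left->guard && left->prev && left->next &&
          !left->prev->guard && !left->next->guard &&
          key_of(left) == key_of(left->prev) &&
          key_of(left) == key_of(left->next)) {
        table[dkey(left->prev)] = left->prev;
      }
    }
    left->next = right;
    right->prev = left;
  }

  void insert_after(Sym *s, Sym *ns) {
    join(ns, s->next);
    join(s, ns);
  }

  // Unlink s from its list and release its bookkeeping (not its memory;
  // freed in the destructor).
  void unlink(Sym *s) {
    join(s->prev, s->next);
    if (!s->guard) {
      delete_digram(s);
      if (s->rule) s->rule->count--;
    }
    s->next = s->prev = nullptr;
  }

  // Check the digram starting at s against the index; handle a repeat.
  // Returns true when the digram was already present somewhere.
  bool check(Sym *s) {
    if (s->guard || s->next == nullptr || s->next->guard) return false;
    Key k = dkey(s);
    std::map<Key, Sym *>::iterator it = table.find(k);
    if (it == table.end()) {
      table[k] = s;
      return false;
    }
    Sym *m = it->second;
    if (m == s) return false;
    if (m->next != s) match(s, m);  // overlapping repeats are left alone
    return true;
  }

  // Replace the digram starting at s (and its partner) by rule r.
  void substitute(Sym *s, Rule *r) {
    Sym *q = s->prev;
    unlink(q->next);
    unlink(q->next);
    insert_after(q, new_nonterminal(r));
    if (!check(q)) check(q->next);
  }

  // The digram at s repeats the one at m; enforce digram uniqueness.
  void match(Sym *s, Sym *m) {
    Rule *r;
    if (m->prev->guard && m->next->next->guard) {
      // m is the whole body of an existing length-2 rule: reuse it.
      r = m->prev->owner;
      substitute(s, r);
    } else {
      r = new_rule();
      append(r, copy_sym(s));
      append(r, copy_sym(s->next));
      substitute(m, r);
      substitute(s, r);
      table[dkey(r->guard->next)] = r->guard->next;
    }
    // Rule utility: inline a sub-rule that is now referenced only once.
    Sym *f = r->guard->next;
    if (f->rule && f->rule->count == 1) expand(f);
  }

  Sym *copy_sym(Sym *s) {
    return s->rule ? new_nonterminal(s->rule) : new_terminal(s->value);
  }

  void append(Rule *r, Sym *s) {
    insert_after(r->guard->prev, s);
  }

  // Inline the body of s's rule in place of s (rule referenced once).
  void expand(Sym *s) {
    Sym *left = s->prev;
    Sym *right = s->next;
    Rule *r = s->rule;
    Sym *f = r->guard->next;
    Sym *l = r->guard->prev;
    delete_digram(s);
    r->alive = false;
    r->count--;
    join(left, f);
    join(l, right);
    table[dkey(l)] = l;
    s->next = s->prev = nullptr;
  }

  Rule *run(const Rcpp::IntegerVector &input) {
    Rule *S = new_rule();
    for (R_xlen_t i = 0; i < input.size(); ++i) {
      append(S, new_terminal(static_cast<long>(input[i])));
      check(S->guard->prev->prev);  // digram ending at the new symbol
    }
    return S;
  }
};

}  // namespace

// Induce a grammar over positive integer codes. Returns a list of rule
// bodies (start rule first, remaining rules in creation order): terminals
// as their positive codes, non-terminal references as -j where j is the
// 1-based position of the referenced rule among the non-start rules.
// [[Rcpp::export(name = ".sequitur_induce")]]
Rcpp::List sequitur_induce(Rcpp::IntegerVector input) {
  if (input.size() < 1) Rcpp::stop("empty input sequence");
  for (R_xlen_t i = 0; i < input.size(); ++i) {
    if (input[i] == NA_INTEGER || input[i] <= 0)
      Rcpp::stop("symbol codes must be positive integers");
  }
  Sequitur seq;
  Rule *S = seq.run(input);

  // Renumber surviving rules: S -> 0, others -> 1..K in creation order.
  std::map<long, int> renum;
  std::vector<Rule *> alive;
  renum[S->id] = 0;
  alive.push_back(S);
  for (Rule *r : seq.all_rules) {
    if (r->alive && r != S) {
      renum[r->id] = static_cast<int>(alive.size());
      alive.push_back(r);
    }
  }

  Rcpp::List out(alive.size());
  for (size_t k = 0; k < alive.size(); ++k) {
    std::vector<int> body;
    for (Sym *s = alive[k]->guard->next; !s->guard; s = s->next) {
      if (s->rule) {
        body.push_back(-renum[s->rule->id]);
      } else {
        body.push_back(static_cast<int>(s->value));
      }
    }
    out[k] = Rcpp::IntegerVector(body.begin(), body.end());
  }
  return out;
}

// Count occurrences of pat in x, greedy left-to-right. With overlap = false
// a match consumes its symbols before scanning resumes.
// [[Rcpp::export(name = ".count_occurrences")]]
int count_occurrences(Rcpp::IntegerVector x, Rcpp::IntegerVector pat,
                      bool overlap) {
  R_xlen_t n = x.size(), m = pat.size();
  if (m == 0 || m > n) return 0;
  int count = 0;
  R_xlen_t i = 0;
  while (i + m <= n) {
    bool hit = true;
    for (R_xlen_t j = 0; j < m; ++j) {
      if (x[i + j] != pat[j]) {
        hit = false;
        break;
      }
    }
    if (hit) {
      ++count;
      i += overlap ? 1 : m;
    } else {
      ++i;
    }
  }
  return count;
}
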