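// Core sequence machinery: 2-bit k-mer encoding, canonical counting,
// compartment classification, read-graph clustering, de Bruijn assembly,
// Jukes-Cantor mutation and paired-end read simulation.
//
// k-mers are packed 2 bits/base into a uint64_t and returned to R as
// doubles; exact round-trip therefore requires 2k <= 52, i.e. k <= 26.
// All randomness goes through the R RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>
#include <array>
#include <cstring>
#include <climits>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline uint64_t revcomp_bits(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL ^ (x & 3ULL));
    x >>= 2;
  }
  return r;
}

static void check_k(int k, bool need_numeric = true) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  if (need_numeric && k > 26)
    stop("k > 26 cannot be represented exactly in a numeric k-mer code; use k <= 26");
}

// Append (canonical) k-mer codes of one sequence to `out`.
// canonical: min(fwd, revcomp); otherwise forward-strand codes.
static void kmers_of(const char* s, size_t n, int k, bool canonical,
                     std::vector<uint64_t>& out) {
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 ^ b)) << shift);
    if (++valid >= k)
      out.push_back(canonical ? std::min(fwd, rev) : fwd);
  }
}

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k, bool canonical = true) {
  check_k(k);
  std::vector<uint64_t> all;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    kmers_of(s, strlen(s), k, canonical, all);
  }
  std::sort(all.begin(), all.end());
  size_t m = all.size(), nd = 0;
  for (size_t i = 0; i < m; ) {
    size_t j = i + 1;
    while (j < m && all[j] == all[i]) ++j;
    ++nd; i = j;
  }
  NumericVector km(nd), ct(nd);
  size_t p = 0;
  for (size_t i = 0; i < m; ) {
    size_t j = i + 1;
    while (j < m && all[j] == all[i]) ++j;
    km[p] = (double)all[i];
    ct[p] = (double)(j - i);
    ++p; i = j;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// Forward-strand k-mer codes with their 1-based start positions.
// [[Rcpp::export]]
List seq_kmer_pos_cpp(std::string s, int k) {
  check_k(k);
  std::vector<double> km;
  std::vector<int> pos;
  size_t n = s.size();
  if (n >= (size_t)k) {
    const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t fwd = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        km.push_back((double)fwd);
        pos.push_back((int)(i - k + 2));
      }
    }
  }
  return List::create(_["kmer"] = NumericVector(km.begin(), km.end()),
                      _["pos"] = IntegerVector(pos.begin(), pos.end()));
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  check_k(k);
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t x = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) { buf[j] = BASES[x & 3ULL]; x >>= 2; }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector encode_kmers_cpp(CharacterVector kmers, int k, bool canonical = true) {
  check_k(k);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)strlen(s) != k) stop("k-mer length mismatch");
    uint64_t x = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) stop("non-ACGT base in k-mer");
      x = (x << 2) | (uint64_t)b;
    }
    if (canonical) x = std::min(x, revcomp_bits(x, k));
    out[i] = (double)x;
  }
  return out;
}

// Shared-fraction classification. For every read, the fraction of its
// distinct canonical k-mers found in each reference class's k-mer set.
// Returns n_reads x n_class matrix plus per-read distinct k-mer counts.
// [[Rcpp::export]]
List classify_frac_cpp(CharacterVector reads, CharacterVector ref_seqs,
                       IntegerVector ref_class, int n_class, int k) {
  check_k(k);
  if (n_class > 64) stop("at most 64 reference classes supported");
  std::unordered_map<uint64_t, uint64_t> idx; // canonical k-mer -> class bitmask
  std::vector<uint64_t> buf;
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) {
    buf.clear();
    const char* s = CHAR(STRING_ELT(ref_seqs, i));
    kmers_of(s, strlen(s), k, true, buf);
    uint64_t bit = 1ULL << ref_class[i];
    for (uint64_t km : buf) idx[km] |= bit;
  }
  R_xlen_t nr = reads.size();
  NumericMatrix frac(nr, n_class);
  IntegerVector nk(nr);
  std::vector<uint64_t> rk;
  std::vector<int> hits(n_class);
  for (R_xlen_t i = 0; i < nr; ++i) {
    rk.clear();
    const char* s = CHAR(STRING_ELT(reads, i));
    kmers_of(s, strlen(s), k, true, rk);
    std::sort(rk.begin(), rk.end());
    rk.erase(std::unique(rk.begin(), rk.end()), rk.end());
    std::fill(hits.begin(), hits.end(), 0);
    for (uint64_t km : rk) {
      auto it = idx.find(km);
      if (it == idx.end()) continue;
      uint64_t m = it->second;
      while (m) {
        int c = __builtin_ctzll(m);
        ++hits[c];
        m &= m - 1;
      }
    }
    nk[i] = (int)rk.size();
    if (!rk.empty())
      for (int c = 0; c < n_class; ++c)
        frac(i, c) = (double)hits[c] / (double)rk.size();
  }
  return List::create(_["frac"] = frac, _["n_kmers"] = nk);
}

// ---- union-find ----
struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
};

// k-mer similarity graph clustering: edge between reads sharing >= min_shared
// distinct canonical k-mers; returns 1-based connected-component labels.
// [[Rcpp::export]]
IntegerVector cluster_reads_cpp(CharacterVector reads, int k, int min_shared) {
  check_k(k);
  int n = (int)reads.size();
  std::vector<std::vector<uint64_t>> rk(n);
  std::unordered_map<uint64_t, std::vector<int>> bucket;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    kmers_of(s, strlen(s), k, true, rk[i]);
    std::sort(rk[i].begin(), rk[i].end());
    rk[i].erase(std::unique(rk[i].begin(), rk[i].end()), rk[i].end());
    for (uint64_t km : rk[i]) bucket[km].push_back(i);
  }
  DSU dsu(n);
  std::unordered_map<int, int> cnt;
  for (int i = 0; i < n; ++i) {
    cnt.clear();
    for (uint64_t km : rk[i]) {
      const std::vector<int>& b = bucket[km];
      for (int j : b)
        if (j > i && dsu.find(j) != dsu.find(i)) ++cnt[j];
    }
    for (auto& pr : cnt)
      if (pr.second >= min_shared) dsu.unite(i, pr.first);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = dsu.find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}

// ---- de Bruijn assembly of high-copy compartments ----
//
// Nodes are (k-1)-mers, edges are k-mers with count >= threshold; the count
// map holds forward-strand k-mers of every read AND its reverse complement,
// so each genomic locus is counted twice per covering read and the graph is
// strand-symmetric. Contigs are walked along unique successors; a walk that
// returns to its start edge is circular.

// [[Rcpp::export]]
List assemble_cpp(CharacterVector reads, int k, double threshold,
                  int max_contigs = 32, int min_contig_len = 0) {
  check_k(k, false);
  if (k > 31) stop("k must be <= 31 for assembly");
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const uint64_t nmask = (1ULL << (2 * (k - 1))) - 1ULL;
  std::unordered_map<uint64_t, int> cnt;
  std::vector<uint64_t> buf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    buf.clear();
    const char* s = CHAR(STRING_ELT(reads, i));
    kmers_of(s, strlen(s), k, false, buf); // forward strand
    for (uint64_t km : buf) {
      ++cnt[km];
      ++cnt[revcomp_bits(km, k)];
    }
  }
  // auto threshold: the dominant coverage mode is located as the
  // mass-weighted median k-mer count (the high-copy compartment holds most
  // of the k-mer mass by construction); the threshold is the middle of the
  // valley (argmin plateau) of the count histogram below that mode.
  if (threshold < 0) {
    const int HMAX = 4000;
    std::vector<double> hist(HMAX + 1, 0.0);
    double total_mass = 0.0;
    for (auto& pr : cnt) {
      int c = std::min(pr.second, HMAX);
      hist[c] += 1.0;
      total_mass += c;
    }
    // 75th mass percentile: robustly inside the high-copy mode whenever
    // the boosted compartment holds >= 25% of total k-mer mass
    double acc = 0.0; int c_hi = 2;
    for (int c = 1; c <= HMAX; ++c) {
      acc += hist[c] * c;
      if (acc >= 0.75 * total_mass) { c_hi = c; break; }
    }
    std::vector<double> sm(HMAX + 1, 0.0);
    for (int c = 1; c <= HMAX; ++c) {
      double s = 0; int n = 0;
      for (int d = -2; d <= 2; ++d)
        if (c + d >= 1 && c + d <= HMAX) { s += hist[c + d]; ++n; }
      sm[c] = s / n;
    }
    int lo = std::max(2, c_hi / 10);
    double mn = R_PosInf;
    for (int c = lo; c < c_hi; ++c) mn = std::min(mn, sm[c]);
    int first = -1, last = -1;
    for (int c = lo; c < c_hi; ++c)
      if (sm[c] <= mn + 1e-9) { if (first < 0) first = c; last = c; }
    threshold = (first < 0) ? std::max(3.0, c_hi / 4.0) : (first + last) / 2.0;
    if (threshold < 3) threshold = 3;
  }
  std::unordered_set<uint64_t> edges;
  for (auto& pr : cnt)
    if (pr.second >= threshold) edges.insert(pr.first);
  if (edges.size() > 3000000)
    stop("depth threshold %.1f keeps %d k-mers; graph too large (threshold too low?)",
         threshold, (int)edges.size());

  std::unordered_set<uint64_t> used;
  std::vector<std::string> contigs;
  std::vector<bool> circ;
  std::vector<double> depth;
  int n_branch = 0;

  auto decode_node = [&](uint64_t node) {
    std::string s(k - 1, 'A');
    for (int j = k - 2; j >= 0; --j) { s[j] = BASES[node & 3ULL]; node >>= 2; }
    return s;
  };

  while ((int)contigs.size() < max_contigs) {
    // start from the unused edge with the highest count
    uint64_t start = 0; int bestc = -1;
    for (const uint64_t e : edges) {
      if (used.count(e)) continue;
      int c = cnt[e];
      if (c > bestc) { bestc = c; start = e; }
    }
    if (bestc < 0) break;

    std::string fwd_bases;  // bases appended forward of start edge
    std::string bwd_bases;  // bases prepended (built reversed)
    bool circular = false;
    double dsum = (double)cnt[start];
    int dn = 1;
    used.insert(start);
    used.insert(revcomp_bits(start, k));

    // forward walk
    uint64_t node = start & nmask; // suffix (k-1)-mer
    while (true) {
      int nsucc = 0; uint64_t succ = 0;
      for (uint64_t b = 0; b < 4; ++b) {
        uint64_t e = ((node << 2) | b) & mask;
        if (edges.count(e)) { ++nsucc; succ = e; }
      }
      if (nsucc == 0) break;
      if (nsucc > 1) { ++n_branch; break; }
      if (succ == start) { circular = true; break; }
      if (used.count(succ)) break;
      used.insert(succ);
      used.insert(revcomp_bits(succ, k));
      dsum += (double)cnt[succ]; ++dn;
      fwd_bases.push_back(BASES[succ & 3ULL]);
      node = succ & nmask;
    }
    // backward walk (skip if circular)
    if (!circular) {
      uint64_t bnode = start >> 2; // prefix (k-1)-mer
      while (true) {
        int npred = 0; uint64_t pred = 0;
        for (uint64_t b = 0; b < 4; ++b) {
          uint64_t e = (b << (2 * (k - 1))) | bnode;
          if (edges.count(e)) { ++npred; pred = e; }
        }
        if (npred == 0) break;
        if (npred > 1) { ++n_branch; break; }
        if (used.count(pred)) break;
        used.insert(pred);
        used.insert(revcomp_bits(pred, k));
        dsum += (double)cnt[pred]; ++dn;
        bwd_bases.push_back(BASES[(pred >> (2 * (k - 1))) & 3ULL]);
        bnode = pred >> 2;
      }
    }
    std::string contig;
    if (circular) {
      // one base per edge of the cycle: start node + forward bases
      contig = decode_node(start >> 2);
      contig.push_back(BASES[start & 3ULL]);
      contig += fwd_bases;
      // trim the duplicated (k-1) prefix/suffix of a full cycle
      contig = contig.substr(k - 1);
    } else {
      std::reverse(bwd_bases.begin(), bwd_bases.end());
      contig = bwd_bases + decode_node(start >> 2);
      contig.push_back(BASES[start & 3ULL]);
      contig += fwd_bases;
    }
    if ((int)contig.size() >= min_contig_len) {
      contigs.push_back(contig);
      circ.push_back(circular);
      // every covering read contributes once to each strand's key, so the
      // per-strand count is already the read-level k-mer depth
      depth.push_back(dsum / dn);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["contig"] = wrap(contigs),
                      _["circular"] = wrap(circ),
                      _["depth"] = wrap(depth),
                      _["threshold"] = threshold,
                      _["n_branch"] = n_branch);
}

// Booth's least-rotation, applied to both strands; returns the
// lexicographically smallest rotation of min(seq, revcomp(seq)).
static std::string least_rotation(const std::string& s) {
  int n = (int)s.size();
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int kk = 0;
  for (int j = 1; j < 2 * n; ++j) {
    int i = f[j - kk - 1];
    while (i != -1 && t[j] != t[kk + i + 1]) {
      if (t[j] < t[kk + i + 1]) kk = j - i - 1;
      i = f[i];
    }
    if (t[j] != t[kk + i + 1]) {
      if (t[j] < t[kk]) kk = j;
      f[j - kk] = -1;
    } else f[j - kk] = i + 1;
  }
  return t.substr(kk, n);
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) { return revcomp_str(s); }

// [[Rcpp::export]]
std::string min_rotation_cpp(std::string s) {
  if (s.empty()) return s;
  std::string a = least_rotation(s);
  std::string b = least_rotation(revcomp_str(s));
  return std::min(a, b);
}

// ---- simulation primitives (R RNG) ----

// [[Rcpp::export]]
std::string jc_mutate_cpp(std::string s, double p) {
  if (p <= 0) return s;
  for (size_t i = 0; i < s.size(); ++i) {
    if (unif_rand() < p) {
      int b = base2bits(s[i]);
      if (b < 0) continue;
      int nb = (b + 1 + (int)(unif_rand() * 3.0)) & 3;
      s[i] = BASES[nb];
    }
  }
  return s;
}

// [[Rcpp::export]]
std::string random_seq_cpp(int n, double gc) {
  std::string s(n, 'A');
  double half_gc = gc / 2.0, half_at = (1.0 - gc) / 2.0;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < half_at) s[i] = 'A';
    else if (u < 2 * half_at) s[i] = 'T';
    else if (u < 2 * half_at + half_gc) s[i] = 'G';
    else s[i] = 'C';
  }
  return s;
}

// Paired-end simulation from one (possibly circular) template.
// Fragment starts uniform; insert ~ Normal(insert_mean, insert_sd) truncated
// to [read_len, L]; the fragment's sequenced strand is random. r1 = 5' end of
// the fragment on its strand, r2 = revcomp of the fragment's 3' end.
// Returns fragment start (1-based on the template) and insert length so the
// caller can assign truth labels by template position.
// [[Rcpp::export]]
List sim_reads_cpp(std::string tmpl, bool circular, int n_pairs, int read_len,
                   double insert_mean, double insert_sd, double error_rate) {
  int L = (int)tmpl.size();
  if (L < read_len) stop("template shorter than read length");
  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector start(n_pairs), ins_out(n_pairs);
  std::string frag;
  for (int i = 0; i < n_pairs; ++i) {
    int ins = (int)std::lround(norm_rand() * insert_sd + insert_mean);
    if (ins < read_len) ins = read_len;
    if (ins > L) ins = L;
    int st;
    if (circular) st = (int)(unif_rand() * L);
    else st = (int)(unif_rand() * (L - ins + 1));
    if (st >= L) st = L - 1;
    frag.resize(ins);
    for (int j = 0; j < ins; ++j) frag[j] = tmpl[(st + j) % L];
    bool flip = unif_rand() < 0.5;
    if (flip) frag = revcomp_str(frag);
    std::string a = frag.substr(0, read_len);
    std::string b = revcomp_str(frag.substr(ins - read_len));
    if (error_rate > 0) {
      a = jc_mutate_cpp(a, error_rate);
      b = jc_mutate_cpp(b, error_rate);
    }
    r1[i] = a; r2[i] = b;
    start[i] = st + 1;
    ins_out[i] = ins;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2,
                      _["start"] = start, _["insert"] = ins_out);
}

// ---- consensus building helpers ----

// Place reads on a consensus by exact shared k-mers (both strands).
// offset = alignment start of the read in consensus coordinates (1-based,
// may be < 1); strand +1/-1; votes = anchors supporting the best placement.
// [[Rcpp::export]]
List place_reads_cpp(std::string consensus, CharacterVector reads, int k,
                     int max_pos_per_kmer = 8) {
  check_k(k);
  std::unordered_map<uint64_t, std::vector<int>> cpos;
  {
    List kp = seq_kmer_pos_cpp(consensus, k);
    NumericVector km = kp["kmer"];
    IntegerVector ps = kp["pos"];
    for (R_xlen_t i = 0; i < km.size(); ++i) {
      std::vector<int>& v = cpos[(uint64_t)km[i]];
      if ((int)v.size() < max_pos_per_kmer) v.push_back(ps[i]);
    }
  }
  int n = (int)reads.size();
  IntegerVector off(n), votes(n), strand(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int best_v = 0, best_off = NA_INTEGER, best_str = 0;
    for (int sgn = 0; sgn < 2; ++sgn) {
      std::string q = sgn == 0 ? rd : revcomp_str(rd);
      List kp = seq_kmer_pos_cpp(q, k);
      NumericVector km = kp["kmer"];
      IntegerVector ps = kp["pos"];
      std::unordered_map<int, int> vote;
      for (R_xlen_t j = 0; j < km.size(); ++j) {
        auto it = cpos.find((uint64_t)km[j]);
        if (it == cpos.end()) continue;
        for (int cp : it->second) ++vote[cp - ps[j] + 1];
      }
      for (auto& pr : vote)
        if (pr.second > best_v) {
          best_v = pr.second; best_off = pr.first;
          best_str = sgn == 0 ? 1 : -1;
        }
    }
    off[i] = best_off; votes[i] = best_v; strand[i] = best_str;
  }
  return List::create(_["offset"] = off, _["strand"] = strand,
                      _["votes"] = votes);
}

// Majority-vote consensus over placed reads. Ties broken lexicographically
// (A < C < G < T). Returns the consensus string over columns with
// coverage >= min_cov (the maximal covered run containing the seed span).
// [[Rcpp::export]]
List majority_consensus_cpp(CharacterVector reads, IntegerVector offset,
                            IntegerVector strand, int min_cov = 1,
                            int max_span = 20000) {
  int n = (int)reads.size();
  int lo = INT_MAX, hi = INT_MIN;
  for (int i = 0; i < n; ++i) {
    if (offset[i] == NA_INTEGER || strand[i] == 0) continue;
    int len = (int)strlen(CHAR(STRING_ELT(reads, i)));
    lo = std::min(lo, (int)offset[i]);
    hi = std::max(hi, (int)offset[i] + len - 1);
  }
  if (lo > hi) return List::create(_["consensus"] = "", _["coverage"] = IntegerVector(0));
  if (hi - lo + 1 > max_span) hi = lo + max_span - 1;
  int span = hi - lo + 1;
  std::vector<std::array<int, 4>> col(span, {0, 0, 0, 0});
  for (int i = 0; i < n; ++i) {
    if (offset[i] == NA_INTEGER || strand[i] == 0) continue;
    std::string rd(CHAR(STRING_ELT(reads, i)));
    if (strand[i] < 0) rd = revcomp_str(rd);
    for (size_t j = 0; j < rd.size(); ++j) {
      int c = (int)offset[i] - lo + (int)j;
      if (c < 0 || c >= span) continue;
      int b = base2bits(rd[j]);
      if (b >= 0) ++col[c][b];
    }
  }
  std::string cons;
  IntegerVector cov(span);
  for (int c = 0; c < span; ++c) {
    int tot = col[c][0] + col[c][1] + col[c][2] + col[c][3];
    cov[c] = tot;
    int best = 0;
    for (int b = 1; b < 4; ++b)
      if (col[c][b] > col[c][best]) best = b; // strict > keeps lexicographic tie
    cons.push_back(tot >= min_cov ? BASES[best] : 'N');
  }
  // trim leading/trailing N (below min_cov)
  size_t a = cons.find_first_not_of('N');
  size_t b = cons.find_last_not_of('N');
  std::string trimmed = (a == std::string::npos) ? "" : cons.substr(a, b - a + 1);
  return List::create(_["consensus"] = trimmed, _["coverage"] = cov,
                      _["start"] = lo + (a == std::string::npos ? 0 : (int)a));
}

// Mismatch fraction between s[1..n-shift] and s[shift+1..n] for each shift.
// [[Rcpp::export]]
NumericVector shift_mismatch_cpp(std::string s, int max_shift) {
  int n = (int)s.size();
  max_shift = std::min(max_shift, n - 1);
  NumericVector out(std::max(max_shift, 0));
  for (int sh = 1; sh <= max_shift; ++sh) {
    int ov = n - sh, mm = 0;
    for (int i = 0; i < ov; ++i)
      if (s[i] != s[i + sh]) ++mm;
    out[sh - 1] = ov > 0 ? (double)mm / ov : 1.0;
  }
  return out;
}

// Size of intersection of two sorted unique numeric vectors.
// [[Rcpp::export]]
double inter_size_cpp(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Hamming mismatch count between equal-length strings.
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}
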