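#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// State-kind codes used in returned path matrices.
enum PathKind { PK_M = 1, PK_I = 2, PK_D = 3, PK_L = 4, PK_R = 5 };

// Predecessor type codes stored in traceback tables.
enum PredType { PT_M = 0, PT_I = 1, PT_D = 2, PT_L = 3, PT_START = 4 };

// Realign one query read against a genome model made of m subsequences.
// Subsequences with repeat_flag TRUE may be traversed cyclically any number
// of times (zero included, via the free boundary skip), and admit rotating
// multi-base deletions of length l in 1..|G_j|-1 ending at any unit phase.
// Total penalty is minimized; p_match is typically negative (a reward).
//
// Alignment semantics are "fitting": unaligned model prefix/suffix are free,
// the read must be fully consumed by matches, insertions and (flat-penalty)
// clips.  Ties are broken by candidate evaluation order (match states first,
// then deletions, insertions, clips; smaller positions first), making
// tracebacks deterministic.
//
// materialize_dmulti selects between the closed-form on-demand evaluation of
// multi-deletion states (penalty of the single-deletion state at the block
// start plus (l-1) extension charges) and an explicit l-indexed recurrence
// that stores every multi-deletion state; both must agree state-for-state.
// [[Rcpp::export]]
List dp_realign_cpp(std::string read,
                    std::vector<std::string> seqs,
                    LogicalVector repeat_flag,
                    NumericVector p_match, NumericVector p_mismatch,
                    NumericVector p_ins_open, NumericVector p_ins_ext,
                    NumericVector p_del_open, NumericVector p_del_ext,
                    double p_clip, bool clip_enabled,
                    bool materialize_dmulti) {
  const int nR = (int) read.size();
  const int m = (int) seqs.size();
  if (nR < 1) stop("read must have at least one base");
  if (m < 1) stop("model must have at least one subsequence");

  // Flatten the model.
  std::vector<int> off(m), len(m), rep(m);
  int N = 0;
  for (int j = 0; j < m; ++j) {
    len[j] = (int) seqs[j].size();
    if (len[j] < 1) stop("empty subsequence in model");
    off[j] = N;
    N += len[j];
    rep[j] = repeat_flag[j] ? 1 : 0;
  }
  std::string flat;
  flat.reserve(N);
  std::vector<int> subof(N), kof(N); // kof is 1-based position within subsequence
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < len[j]; ++k) {
      flat.push_back(seqs[j][k]);
      subof[off[j] + k] = j;
      kof[off[j] + k] = k + 1;
    }

  // DP tables, rows i = 1..nR.
  const size_t tot = (size_t) nR * N;
  std::vector<double> M(tot, INF), I(tot, INF), D(tot, INF);
  std::vector<signed char> tbM_type(tot, PT_START), tbI_type(tot, PT_M);
  std::vector<int> tbM_p(tot, -1), tbD_p0(tot, -1), tbD_l(tot, 0);
  long long n_updates = 0;

  auto idx = [N](int i, int p) { return (size_t)(i - 1) * N + p; };

  // Per-row boundary bests: best predecessor among tails of preceding
  // subsequences, scanning back until the first B=0 subsequence (inclusive)
  // or the model start; B=1 subsequences passed over contribute their tails
  // and may be skipped at no charge.  Computed incrementally (amortized).
  std::vector<double> bb_val(m, INF);
  std::vector<signed char> bb_type(m, PT_M);
  std::vector<int> bb_p(m, -1);

  // Best match-state value in rows 1..nR-1 (for right-clip terminal).
  double bestRC_val = INF;
  int bestRC_i = -1, bestRC_p = -1;

  // Scratch for materialized multi-deletion states of one subsequence/row.
  std::vector<double> Dm; // (l-1)*len + k indexing within a repeat sub

  for (int i = 1; i <= nR; ++i) {
    const char rb = read[i - 1];

    // Boundary bests from row i-1 (entry candidates for k == 1 states).
    if (i > 1) {
      for (int j = 0; j < m; ++j) {
        double bv = INF;
        signed char bt = PT_M;
        int bp = -1;
        if (j > 0) {
          // Earlier subsequences first (smaller positions win ties).
          if (rep[j - 1] && std::isfinite(bb_val[j - 1])) {
            bv = bb_val[j - 1]; bt = bb_type[j - 1]; bp = bb_p[j - 1];
          }
          const int tp = off[j - 1] + len[j - 1] - 1;
          const size_t t = idx(i - 1, tp);
          ++n_updates;
          if (M[t] < bv) { bv = M[t]; bt = PT_M; bp = tp; }
          ++n_updates;
          if (D[t] < bv) { bv = D[t]; bt = PT_D; bp = tp; }
          ++n_updates;
          if (I[t] < bv) { bv = I[t]; bt = PT_I; bp = tp; }
        }
        bb_val[j] = bv; bb_type[j] = bt; bb_p[j] = bp;
      }
    }

    // Match / mismatch states.
    for (int p = 0; p < N; ++p) {
      const int j = subof[p];
      const int k = kof[p];
      const double sub = (rb == flat[p]) ? p_match[j] : p_mismatch[j];
      double best;
      signed char bt;
      int bp;
      if (i == 1) {
        best = 0.0; bt = PT_START; bp = -1; // free model prefix
      } else {
        best = INF; bt = PT_START; bp = -1;
        auto consider = [&](double v, signed char t, int pp) {
          ++n_updates;
          if (v < best) { best = v; bt = t; bp = pp; }
        };
        if (k > 1) {
          const size_t d = idx(i - 1, p - 1);
          consider(M[d], PT_M, p - 1);
          consider(D[d], PT_D, p - 1);
          consider(I[d], PT_I, p - 1);
        } else {
          if (rep[j] && len[j] > 1) {
            // Cyclic re-entry from the tail of the same unit.
            const int tp = off[j] + len[j] - 1;
            const size_t d = idx(i - 1, tp);
            consider(M[d], PT_M, tp);
            consider(D[d], PT_D, tp);
            consider(I[d], PT_I, tp);
          } else if (rep[j] && len[j] == 1) {
            // Single-base unit: the cyclic predecessor is the cell itself.
            const size_t d = idx(i - 1, p);
            consider(M[d], PT_M, p);
            consider(I[d], PT_I, p);
          }
          consider(bb_val[j], bb_type[j], bb_p[j]);
        }
        if (clip_enabled) consider(p_clip, PT_L, -1); // left clip of 1..i-1
      }
      const size_t c = idx(i, p);
      if (std::isfinite(best)) {
        M[c] = best + sub;
        tbM_type[c] = bt;
        tbM_p[c] = bp;
      }
    }

    // Insertion states (read base i inserted after model position p).
    if (i > 1) {
      for (int p = 0; p < N; ++p) {
        const int j = subof[p];
        const size_t d = idx(i - 1, p), c = idx(i, p);
        double vo = M[d] + p_ins_open[j];
        double ve = I[d] + p_ins_ext[j];
        n_updates += 2;
        if (vo <= ve) { I[c] = vo; tbI_type[c] = PT_M; }
        else          { I[c] = ve; tbI_type[c] = PT_I; }
      }
    }

    // Deletion states (same-row chains opened from match states).
    for (int j = 0; j < m; ++j) {
      const int n = len[j];
      if (!rep[j]) {
        for (int k = 2; k <= n; ++k) { // no predecessor at k == 1
          const int p = off[j] + k - 1;
          const size_t c = idx(i, p);
          double vo = M[idx(i, p - 1)] + p_del_open[j];
          n_updates += 2;
          double ve = (k > 2) ? D[idx(i, p - 1)] + p_del_ext[j] : INF;
          if (vo <= ve) { D[c] = vo; tbD_p0[c] = p - 1; tbD_l[c] = 1; }
          else {
            D[c] = ve;
            tbD_p0[c] = tbD_p0[idx(i, p - 1)];
            tbD_l[c] = tbD_l[idx(i, p - 1)] + 1;
          }
        }
      } else if (n >= 2) {
        // Rotating deletions of l in 1..n-1 unit positions ending at phase k,
        // opened from the match state at phase (k - l) mod n.
        if (!materialize_dmulti) {
          for (int k = 1; k <= n; ++k) {
            const int p = off[j] + k - 1;
            const size_t c = idx(i, p);
            double best = INF;
            int bl = 0, bp0 = -1;
            for (int l = 1; l <= n - 1; ++l) {
              const int ph = ((k - l - 1) % n + n) % n; // 0-based pred phase
              const int p0 = off[j] + ph;
              const double v = M[idx(i, p0)] + p_del_open[j] +
                (double)(l - 1) * p_del_ext[j];
              ++n_updates;
              if (v < best) { best = v; bl = l; bp0 = p0; }
            }
            if (std::isfinite(best)) {
              D[c] = best; tbD_p0[c] = bp0; tbD_l[c] = bl;
            }
          }
        } else {
          // Explicit l-recurrence: Dm(l, k) = Dm(l-1, k-1 mod n) + p_de,
          // base Dm(1, k) = M(i, (k-1) mod n) + p_do.
          Dm.assign((size_t)(n - 1) * n, INF);
          for (int k = 1; k <= n; ++k) {
            const int ph = ((k - 2) % n + n) % n;
            Dm[(size_t)(k - 1)] = M[idx(i, off[j] + ph)] + p_del_open[j];
          }
          for (int l = 2; l <= n - 1; ++l)
            for (int k = 1; k <= n; ++k) {
              const int kp = ((k - 2) % n + n) % n; // 0-based phase k-1
              Dm[(size_t)(l - 1) * n + (k - 1)] =
                Dm[(size_t)(l - 2) * n + kp] + p_del_ext[j];
            }
          for (int k = 1; k <= n; ++k) {
            const int p = off[j] + k - 1;
            const size_t c = idx(i, p);
            double best = INF;
            int bl = 0;
            for (int l = 1; l <= n - 1; ++l) {
              const double v = Dm[(size_t)(l - 1) * n + (k - 1)];
              ++n_updates;
              if (v < best) { best = v; bl = l; }
            }
            if (std::isfinite(best)) {
              const int ph = ((k - bl - 1) % n + n) % n;
              D[c] = best; tbD_p0[c] = off[j] + ph; tbD_l[c] = bl;
            }
          }
        }
      }
    }

    // Right-clip bookkeeping (clip may start at any position 2..nR).
    if (i < nR) {
      for (int p = 0; p < N; ++p) {
        const size_t c = idx(i, p);
        ++n_updates;
        if (M[c] < bestRC_val) { bestRC_val = M[c]; bestRC_i = i; bestRC_p = p; }
      }
    }
  }

  // Terminal state: best of match/insertion states at i = nR and right-clip
  // candidates (a path may not end in a deletion).
  double best = INF;
  int term_type = PT_M, term_p = -1;
  for (int p = 0; p < N; ++p) {
    const size_t c = idx(nR, p);
    if (M[c] < best) { best = M[c]; term_type = PT_M; term_p = p; }
  }
  for (int p = 0; p < N; ++p) {
    const size_t c = idx(nR, p);
    if (I[c] < best) { best = I[c]; term_type = PT_I; term_p = p; }
  }
  bool right_clip = false;
  if (clip_enabled && std::isfinite(bestRC_val) && bestRC_val + p_clip < best) {
    best = bestRC_val + p_clip;
    right_clip = true;
  }
  if (!std::isfinite(best)) stop("no valid alignment found");

  // Traceback.
  std::vector<int> rk, ri, rj, rkk, rl; // reversed path rows
  int left_clip_len = 0, right_clip_len = 0;
  int cur_type, cur_i, cur_p;
  if (right_clip) {
    right_clip_len = nR - bestRC_i;
    rk.push_back(PK_R); ri.push_back(bestRC_i + 1);
    rj.push_back(NA_INTEGER); rkk.push_back(NA_INTEGER);
    rl.push_back(right_clip_len);
    cur_type = PT_M; cur_i = bestRC_i; cur_p = bestRC_p;
  } else {
    cur_type = term_type; cur_i = nR; cur_p = term_p;
  }
  while (true) {
    if (cur_type == PT_M) {
      const size_t c = idx(cur_i, cur_p);
      rk.push_back(PK_M); ri.push_back(cur_i);
      rj.push_back(subof[cur_p] + 1); rkk.push_back(kof[cur_p]); rl.push_back(0);
      const signed char pt = tbM_type[c];
      const int pp = tbM_p[c];
      if (pt == PT_START) break;
      if (pt == PT_L) {
        left_clip_len = cur_i - 1;
        rk.push_back(PK_L); ri.push_back(1);
        rj.push_back(NA_INTEGER); rkk.push_back(NA_INTEGER);
        rl.push_back(left_clip_len);
        break;
      }
      cur_type = pt; cur_i = cur_i - 1; cur_p = pp;
    } else if (cur_type == PT_I) {
      const size_t c = idx(cur_i, cur_p);
      rk.push_back(PK_I); ri.push_back(cur_i);
      rj.push_back(subof[cur_p] + 1); rkk.push_back(kof[cur_p]); rl.push_back(0);
      cur_type = tbI_type[c]; cur_i = cur_i - 1; // p unchanged
    } else { // PT_D: same-row deletion run ending at cur_p
      const size_t c = idx(cur_i, cur_p);
      const int l = tbD_l[c], p0 = tbD_p0[c];
      const int j = subof[cur_p];
      if (!rep[j]) {
        for (int p = cur_p; p > p0; --p) {
          rk.push_back(PK_D); ri.push_back(cur_i);
          rj.push_back(j + 1); rkk.push_back(kof[p]); rl.push_back(l);
        }
      } else {
        const int n = len[j];
        const int k = kof[cur_p]; // 1-based end phase
        for (int t = 0; t < l; ++t) {
          const int ph = ((k - 1 - t) % n + n) % n;
          rk.push_back(PK_D); ri.push_back(cur_i);
          rj.push_back(j + 1); rkk.push_back(ph + 1); rl.push_back(l);
        }
      }
      cur_type = PT_M; cur_p = p0; // same row
    }
  }

  const int nrow = (int) rk.size();
  IntegerMatrix path(nrow, 5);
  for (int r = 0; r < nrow; ++r) {
    const int s = nrow - 1 - r;
    path(r, 0) = rk[s]; path(r, 1) = ri[s]; path(r, 2) = rj[s];
    path(r, 3) = rkk[s]; path(r, 4) = rl[s];
  }
  colnames(path) = CharacterVector::create("kind", "i", "j", "k", "l");

  return List::create(
    _["penalty"] = best,
    _["path"] = path,
    _["left_clip"] = left_clip_len,
    _["right_clip"] = right_clip_len,
    _["n_updates"] = (double) n_updates);
}

// Second-pass alignment used when projecting repeat-aligned read fragments
// back to reference coordinates: align a fragment to the reference STR
// region sequence followed by one trailing repeat-unit copy.  The region
// part carries its own (lowered) deletion-open penalty.  anchor_left /
// anchor_right state whether the fragment is bounded by flank-aligned
// segments on that side (anchored: the region must be covered from that
// end; free: fitting semantics).  Positions beyond the region (the trailing
// unit) consume no reference: matches there project as insertions and
// deletions there are dropped.
// [[Rcpp::export]]
List align_fragment_cpp(std::string frag, std::string region, std::string unit,
                        double p_match, double p_mismatch,
                        double p_ins_open, double p_ins_ext,
                        double p_del_open_region, double p_del_open_unit,
                        double p_del_ext,
                        bool anchor_left, bool anchor_right) {
  const int nf = (int) frag.size();
  const int nre = (int) region.size();
  std::string target = region + unit;
  const int T = (int) target.size();
  if (nf < 1) stop("empty fragment");
  if (nre < 1) stop("empty region");

  auto pdo_at = [&](int t) { // t: 1-based target position being deleted
    return (t <= nre) ? p_del_open_region : p_del_open_unit;
  };

  // H: frag[i] aligned to target[t]; E: frag[i] inserted after target[t]
  // (t in 0..T); F: deletion run ending at target[t] after consuming
  // frag[1..i] (i in 0..nf).
  std::vector<double> Hc((size_t)(nf + 1) * (T + 1), INF),
    Ec((size_t)(nf + 1) * (T + 1), INF), Fc((size_t)(nf + 1) * (T + 1), INF);
  std::vector<signed char> tbH((size_t)(nf + 1) * (T + 1), 0),
    tbE((size_t)(nf + 1) * (T + 1), 0), tbF((size_t)(nf + 1) * (T + 1), 0);
  // tb codes: for H, pred of the diagonal move: 0=start,1=H,2=E,3=F
  // for E: 1=H,2=E ; for F: 1=H,3=F
  auto at = [T](int i, int t) { return (size_t) i * (T + 1) + t; };

  // Row i = 0: nothing consumed.
  for (int t = 0; t <= T; ++t) {
    if (anchor_left) {
      if (t == 0) Hc[at(0, 0)] = 0.0; // start marker (no base aligned yet)
      else {
        Fc[at(0, t)] = pdo_at(1) + (double)(t - 1) * p_del_ext;
        tbF[at(0, t)] = 0; // run from target start
      }
    } else {
      Hc[at(0, t)] = 0.0; // free target prefix
    }
  }

  for (int i = 1; i <= nf; ++i) {
    for (int t = 0; t <= T; ++t) {
      // H
      if (t >= 1) {
        const double sub = (frag[i - 1] == target[t - 1]) ? p_match : p_mismatch;
        double best = INF; signed char bt = 1;
        const size_t d = at(i - 1, t - 1);
        if (Hc[d] < best) { best = Hc[d]; bt = 1; }
        if (Fc[d] < best) { best = Fc[d]; bt = 3; }
        if (Ec[d] < best) { best = Ec[d]; bt = 2; }
        if (std::isfinite(best)) { Hc[at(i, t)] = best + sub; tbH[at(i, t)] = bt; }
      }
      // E (ties prefer extending the run: keeps insertions contiguous so the
      // projected CIGAR carries one insertion event)
      {
        const size_t d = at(i - 1, t);
        double vo = Hc[d] + p_ins_open;
        double ve = Ec[d] + p_ins_ext;
        if (ve <= vo) { Ec[at(i, t)] = ve; tbE[at(i, t)] = 2; }
        else          { Ec[at(i, t)] = vo; tbE[at(i, t)] = 1; }
      }
      // F (same row)
      if (t >= 1) {
        double vo = Hc[at(i, t - 1)] + pdo_at(t);
        double ve = Fc[at(i, t - 1)] + p_del_ext;
        if (vo <= ve) { Fc[at(i, t)] = vo; tbF[at(i, t)] = 1; }
        else          { Fc[at(i, t)] = ve; tbF[at(i, t)] = 3; }
      }
    }
  }

  // Terminal.  Ties prefer an insertion ending (keeps repeat overflow
  // adjacent to the trailing unit, i.e. right-aligned, so projection emits
  // one insertion run), then matches, then trailing deletions.
  const int tmin = anchor_right ? nre : 0;
  double best = INF; int bt = 0, bT = -1; // bt: 1=H,2=E,3=F
  for (int t = tmin; t <= T; ++t)
    if (Ec[at(nf, t)] < best) { best = Ec[at(nf, t)]; bt = 2; bT = t; }
  for (int t = tmin; t <= T; ++t)
    if (Hc[at(nf, t)] < best) { best = Hc[at(nf, t)]; bt = 1; bT = t; }
  for (int t = tmin; t <= T; ++t)
    if (Fc[at(nf, t)] < best) { best = Fc[at(nf, t)]; bt = 3; bT = t; }
  if (!std::isfinite(best)) stop("fragment alignment failed");

  // Traceback into projected ops: M/I/D over the region, trailing-unit
  // matches become I, trailing-unit deletions are dropped.  Row 0 H cells
  // are start markers (free or anchored prefix); a row 0 F cell is the
  // anchored leading deletion run covering target 1..t.
  std::vector<char> ops; // reversed
  int i = nf, t = bT, st = bt;
  while (true) {
    if (st == 1) { // H
      if (i == 0) break; // start marker reached
      ops.push_back(t <= nre ? 'M' : 'I');
      st = tbH[at(i, t)];
      --i; --t;
    } else if (st == 2) { // E
      ops.push_back('I');
      st = tbE[at(i, t)];
      --i;
    } else { // F
      if (i == 0) { // anchored leading deletion run spanning target 1..t
        for (; t >= 1; --t) if (t <= nre) ops.push_back('D');
        break;
      }
      if (t <= nre) ops.push_back('D');
      st = (tbF[at(i, t)] == 1) ? 1 : 3;
      --t;
    }
  }

  // Leftmost covered region position (0-based offset into the region): the
  // target position at which the start marker sat.
  int covered_from = t < 0 ? 0 : t;
  if (covered_from > nre) covered_from = nre;

  // Run-length encode (forward order).
  std::vector<char> op_out;
  std::vector<int> len_out;
  for (int q = (int) ops.size() - 1; q >= 0; --q) {
    const char o = ops[q];
    if (!op_out.empty() && op_out.back() == o) ++len_out.back();
    else { op_out.push_back(o); len_out.push_back(1); }
  }

  StringVector opv(op_out.size());
  IntegerVector lenv(op_out.size());
  for (size_t q = 0; q < op_out.size(); ++q) {
    opv[q] = std::string(1, op_out[q]);
    lenv[q] = len_out[q];
  }
  return List::create(
    _["op"] = opv, _["len"] = lenv,
    _["ref_offset"] = covered_from,
    _["penalty"] = best);
}
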