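// Deterministic emulation of the lane-group wavefront alignment kernel:
// p lockstep lanes, k DP columns per lane, a wavefront of m+p iterations in
// which lane t computes row i-t, shuffle-style exchange of each lane's
// rightmost (H, F) to its right neighbour, two-register query-character
// rotation, running maximum with a final lane reduction, and column-chunk
// tiling (l = ceil(n / (k*p)) stages) with a p-slot boundary flush buffer.
//
// Precision modes: 0 = wide32 (exact, never flags), 1 = int16sat (all
// add/sub saturate to [-32768, 32767]; a subject is flagged once any H
// reaches 32767), 2 = fp16emu (exact integer arithmetic below the
// half-float precision-loss region; flags once any H >= 2048).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
#include <cstdint>
using namespace Rcpp;

static const int SENTINEL = INT_MIN / 4;

static inline int cl16(long v) {
  return v > 32767 ? 32767 : (v < -32768 ? -32768 : (int)v);
}

struct HalfResult {
  int score;
  bool flag;
};

struct EngineDebug {
  bool enabled = false;
  std::vector<int> coverage;          // m*n counts, half 0, real cells only
  std::vector<int> schedule;          // (m+p) x p cq_current codes, stage 0
  std::vector<std::vector<int>> boundH; // per stage: store rows 0..m (half 0)
  std::vector<std::vector<int>> boundF;
  long iterations = 0;
  int stages = 0;
};

// Core engine. nh = 1 (plain sigma lookups) or 2 (packed-pair lookups).
// sigma rows/cols cover the full code set including the pad code.
static void engine_run(const std::vector<int>& q,
                       const std::vector<std::vector<int>>& subj,
                       const std::vector<int>& nact,
                       const IntegerMatrix& sigma,
                       const IntegerMatrix& packedTab, int nsym,
                       int pad_code, int alpha, int beta,
                       int p, int k, int mode, bool tiled,
                       std::vector<HalfResult>& res, EngineDebug& dbg) {
  const int nh = (int)subj.size();
  const int m = (int)q.size();
  const int width = p * k;
  int nmax = 0;
  for (int h = 0; h < nh; ++h) nmax = std::max(nmax, nact[h]);
  const int l = tiled ? (nmax + width - 1) / width : 1;
  const int sent = (mode == 1) ? -32768 : SENTINEL;

  // padded subjects, one residue code per column slot
  std::vector<std::vector<int>> sp(nh, std::vector<int>((size_t)l * width, pad_code));
  for (int h = 0; h < nh; ++h)
    for (int j = 0; j < nact[h]; ++j) sp[h][j] = subj[h][j];

  // stage boundary stores, rows 0..m
  std::vector<std::vector<int>> prevH(nh, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int>> prevF(nh, std::vector<int>(m + 1, sent));

  std::vector<int> runmax(nh, 0);
  std::vector<bool> flag(nh, false);

  if (dbg.enabled) {
    dbg.coverage.assign((size_t)m * std::max(nact[0], 1), 0);
    dbg.schedule.assign((size_t)(m + p) * p, NA_INTEGER);
  }

  // per-lane per-half register state (re-initialized every stage)
  std::vector<std::vector<int>> Hup(nh), Ecol(nh);
  std::vector<std::vector<int>> recvH(nh), recvF(nh), prevRecvH(nh);
  std::vector<std::vector<int>> sendH(nh), sendF(nh);
  std::vector<int> cq_cur(p), cq_next(p);

  for (int stage = 0; stage < l; ++stage) {
    for (int h = 0; h < nh; ++h) {
      Hup[h].assign((size_t)p * k, 0);
      Ecol[h].assign((size_t)p * k, sent);
      recvH[h].assign(p, 0);
      recvF[h].assign(p, sent);
      prevRecvH[h].assign(p, 0);
      sendH[h].assign(p, 0);
      sendF[h].assign(p, sent);
    }
    std::fill(cq_cur.begin(), cq_cur.end(), pad_code);
    std::fill(cq_next.begin(), cq_next.end(), pad_code);

    // next-stage boundary store and the p-slot flush buffer
    std::vector<std::vector<int>> newH(nh, std::vector<int>(m + 1, 0));
    std::vector<std::vector<int>> newF(nh, std::vector<int>(m + 1, sent));
    std::vector<std::vector<int>> bufRow(nh), bufH(nh), bufF(nh);

    for (int ii = 0; ii < m + p; ++ii) {
      // --- query-character rotation (two-register scheme) ---
      if (ii % p == 0)
        for (int t = 0; t < p; ++t)
          cq_next[t] = (ii + t < m) ? q[ii + t] : pad_code;
      for (int t = p - 1; t >= 1; --t) cq_cur[t] = cq_cur[t - 1]; // shuffle-up
      cq_cur[0] = cq_next[0];                                     // lane-0 copy
      for (int t = 0; t + 1 < p; ++t) cq_next[t] = cq_next[t + 1]; // shuffle-down
      if (dbg.enabled && stage == 0)
        for (int t = 0; t < p; ++t) dbg.schedule[(size_t)ii * p + t] = cq_cur[t];

      // --- lockstep cell computation: lane t works on row ii - t + 1 ---
      for (int t = 0; t < p; ++t) {
        const int row = ii - t + 1;
        for (int h = 0; h < nh; ++h) {
          int hl, hd, f;
          if (t == 0) { // stage boundary (initialization or previous store)
            hl = (row >= 0 && row <= m) ? prevH[h][row] : 0;
            hd = (row - 1 >= 0 && row - 1 <= m) ? prevH[h][row - 1] : 0;
            f  = (row >= 0 && row <= m) ? prevF[h][row] : sent;
          } else {      // shuffle-exchanged neighbour boundary
            hl = recvH[h][t];
            f  = recvF[h][t];
            hd = prevRecvH[h][t];
          }
          const int cq = cq_cur[t];
          for (int c = 0; c < k; ++c) {
            const size_t reg = (size_t)t * k + c;
            const int colg = stage * width + t * k + c; // 0-based global column
            int sig;
            if (nh == 2) { // one packed lookup yields both halves' scores
              const int pv = packedTab(cq, sp[0][colg] * nsym + sp[1][colg]);
              sig = (h == 0) ? (int)(int16_t)((uint32_t)pv & 0xFFFFu)
                             : (int)(int16_t)((uint32_t)pv >> 16);
            } else {
              sig = sigma(cq, sp[0][colg]);
            }
            int e, fn, hv;
            if (mode == 1) {
              e  = std::max(cl16((long)Ecol[h][reg] - beta),
                            cl16((long)Hup[h][reg] - alpha));
              fn = std::max(cl16((long)f - beta), cl16((long)hl - alpha));
              hv = std::max(std::max(cl16((long)hd + sig), e),
                            std::max(fn, 0));
              if (hv >= 32767) flag[h] = true;
            } else {
              e  = std::max(Ecol[h][reg] - beta, Hup[h][reg] - alpha);
              fn = std::max(f - beta, hl - alpha);
              hv = std::max(std::max(hd + sig, e), std::max(fn, 0));
              if (mode == 2 && hv >= 2048) flag[h] = true;
            }
            if (hv > runmax[h]) runmax[h] = hv;
            hd = Hup[h][reg];
            Hup[h][reg] = hv;
            Ecol[h][reg] = e;
            hl = hv;
            f = fn;
            if (dbg.enabled && h == 0 && row >= 1 && row <= m && colg < nact[0])
              dbg.coverage[(size_t)(row - 1) * nact[0] + colg] += 1;
          }
          sendH[h][t] = hl; // rightmost H of this lane's row
          sendF[h][t] = f;  // rightmost F
        }
      }

      // --- shuffle-up exchange of (H, F); keep previous H for the diagonal ---
      for (int h = 0; h < nh; ++h) {
        for (int t = 0; t < p; ++t) prevRecvH[h][t] = recvH[h][t];
        for (int t = p - 1; t >= 1; --t) {
          recvH[h][t] = sendH[h][t - 1];
          recvF[h][t] = sendF[h][t - 1];
        }
        // boundary flush buffer: lane p-1's values shift in once per iteration
        const int rowOut = ii - p + 2;
        bufRow[h].push_back(rowOut);
        bufH[h].push_back(sendH[h][p - 1]);
        bufF[h].push_back(sendF[h][p - 1]);
        if ((int)bufRow[h].size() == p) { // coalesced block write
          for (size_t b = 0; b < bufRow[h].size(); ++b) {
            const int r = bufRow[h][b];
            if (r >= 1 && r <= m) { newH[h][r] = bufH[h][b]; newF[h][r] = bufF[h][b]; }
          }
          bufRow[h].clear(); bufH[h].clear(); bufF[h].clear();
        }
      }
      dbg.iterations += 1;
    }

    // drain: final (possibly partial) flush at wavefront end
    for (int h = 0; h < nh; ++h) {
      for (size_t b = 0; b < bufRow[h].size(); ++b) {
        const int r = bufRow[h][b];
        if (r >= 1 && r <= m) { newH[h][r] = bufH[h][b]; newF[h][r] = bufF[h][b]; }
      }
      bufRow[h].clear(); bufH[h].clear(); bufF[h].clear();
      prevH[h] = newH[h];
      prevF[h] = newF[h];
    }
    if (dbg.enabled) {
      dbg.boundH.push_back(prevH[0]);
      dbg.boundF.push_back(prevF[0]);
    }
    dbg.stages += 1;
  }

  res.resize(nh);
  for (int h = 0; h < nh; ++h) {
    res[h].score = runmax[h];
    res[h].flag = flag[h];
  }
}

// [[Rcpp::export]]
List cpp_lane_align(IntegerVector q, IntegerVector s,
                    IntegerMatrix sigma, int pad_code,
                    int alpha, int beta, int p, int k, int mode,
                    bool tiled, bool debug = false) {
  std::vector<int> qv(q.begin(), q.end());
  std::vector<std::vector<int>> subj(1, std::vector<int>(s.begin(), s.end()));
  std::vector<int> nact(1, (int)s.size());
  IntegerMatrix dummy(1, 1);
  std::vector<HalfResult> res;
  EngineDebug dbg;
  dbg.enabled = debug;
  engine_run(qv, subj, nact, sigma, dummy, 0, pad_code, alpha, beta,
             p, k, mode, tiled, res, dbg);
  List out = List::create(_["score"] = res[0].score,
                          _["overflow"] = res[0].flag,
                          _["stages"] = dbg.stages,
                          _["iterations"] = (double)dbg.iterations);
  if (debug) {
    const int m = q.size(), n = std::max((int)s.size(), 1);
    IntegerMatrix cov(m, (int)s.size());
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < (int)s.size(); ++j)
        cov(i, j) = dbg.coverage[(size_t)i * n + j];
    IntegerMatrix sched(m + p, p);
    for (int i = 0; i < m + p; ++i)
      for (int t = 0; t < p; ++t) sched(i, t) = dbg.schedule[(size_t)i * p + t];
    List bh(dbg.boundH.size()), bf(dbg.boundF.size());
    for (size_t sidx = 0; sidx < dbg.boundH.size(); ++sidx) {
      bh[sidx] = IntegerVector(dbg.boundH[sidx].begin(), dbg.boundH[sidx].end());
      bf[sidx] = IntegerVector(dbg.boundF[sidx].begin(), dbg.boundF[sidx].end());
    }
    out["coverage"] = cov;
    out["schedule"] = sched;
    out["boundaryH"] = bh;
    out["boundaryF"] = bf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_lane_align_packed(IntegerVector q, IntegerVector s1, IntegerVector s2,
                           IntegerMatrix sigma, IntegerMatrix packedTab,
                           int pad_code, int alpha, int beta,
                           int p, int k, int mode, bool tiled) {
  std::vector<int> qv(q.begin(), q.end());
  std::vector<std::vector<int>> subj(2);
  subj[0].assign(s1.begin(), s1.end());
  subj[1].assign(s2.begin(), s2.end());
  std::vector<int> nact(2);
  nact[0] = (int)s1.size();
  nact[1] = (int)s2.size();
  const int nsym = sigma.nrow();
  std::vector<HalfResult> res;
  EngineDebug dbg;
  engine_run(qv, subj, nact, sigma, packedTab, nsym, pad_code, alpha, beta,
             p, k, mode, tiled, res, dbg);
  return List::create(
    _["score_a"] = res[0].score, _["overflow_a"] = res[0].flag,
    _["score_b"] = res[1].score, _["overflow_b"] = res[1].flag,
    _["stages"] = dbg.stages, _["iterations"] = (double)dbg.iterations);
}

// Batched scoring loop over an encoded database slice: per-sequence lane
// configuration (p, k, tiled) is selected upstream by the length bins.
// [[Rcpp::export]]
List cpp_scan_batch(IntegerVector q, IntegerVector residues,
                    NumericVector offsets, IntegerVector lengths,
                    IntegerVector pv, IntegerVector kv, LogicalVector tiledv,
                    IntegerMatrix sigma, int pad_code,
                    int alpha, int beta, int mode) {
  const int nseq = lengths.size();
  std::vector<int> qv(q.begin(), q.end());
  IntegerMatrix dummy(1, 1);
  IntegerVector scores(nseq);
  LogicalVector flags(nseq);
  std::vector<std::vector<int>> subj(1);
  std::vector<int> nact(1);
  for (int i = 0; i < nseq; ++i) {
    const size_t off = (size_t)offsets[i];
    const int n = lengths[i];
    subj[0].assign(residues.begin() + off, residues.begin() + off + n);
    nact[0] = n;
    std::vector<HalfResult> res;
    EngineDebug dbg;
    engine_run(qv, subj, nact, sigma, dummy, 0, pad_code, alpha, beta,
               pv[i], kv[i], mode, tiledv[i], res, dbg);
    scores[i] = res[0].score;
    flags[i] = res[0].flag;
  }
  return List::create(_["score"] = scores, _["overflow"] = flags);
}
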