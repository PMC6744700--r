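// Dynamic-programming cores: five-pair-state local Viterbi (scalar and
// batched-over-targets), log-space Forward-Backward, Maximum Accuracy
// decoding, and the prefilter alignment kernels.
//
// Score convention: bits (log2). Probability zero is represented by the
// large negative finite sentinel LOG0 so that padded lanes and forbidden
// cells can never win a maximization while staying branch-friendly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG0 = -100000.0;   // Viterbi log2(0) sentinel (bits)
static const double LOG0F = -1e30;      // Forward-Backward log2(0) sentinel

// transition slot order of the L x 7 transition matrices
enum Slot { MM_ = 0, MI_ = 1, MD_ = 2, IM_ = 3, II_ = 4, DM_ = 5, DD_ = 6 };

// pair-state backtrace codes (3 bits); order doubles as tie priority
enum PS { S_STOP = 0, S_MM = 1, S_IM = 2, S_MI = 3, S_GD = 4, S_DG = 5 };

// ---------------------------------------------------------------------------
// Scalar Viterbi, Algorithm-2 style with branches, single-row score
// buffers (one vector per pair state holding the current row up to j-1
// and the previous row from j on).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".viterbi_scalar_cpp")]]
List viterbi_scalar_cpp(NumericMatrix qf, NumericMatrix qtr,
                        NumericMatrix tem, NumericMatrix ttr,
                        Nullable<RawMatrix> cell_off,
                        Nullable<NumericMatrix> ss,
                        bool corrected) {
  const int Lq = qf.nrow(), Lt = tem.nrow();
  const bool use_co = cell_off.isNotNull();
  RawMatrix co;
  if (use_co) co = RawMatrix(cell_off);
  const bool use_ss = ss.isNotNull();
  NumericMatrix ssm;
  if (use_ss) ssm = NumericMatrix(ss);

  std::vector<double> sMM(Lt + 1, LOG0), sMI(Lt + 1, LOG0),
      sIM(Lt + 1, LOG0), sDG(Lt + 1, LOG0), sGD(Lt + 1, LOG0);
  RawMatrix bt(Lq + 1, Lt + 1);
  std::fill(bt.begin(), bt.end(), (Rbyte)0);

  double best = 0.0;
  int ib = 0, jb = 0;
  const int qMDslot = corrected ? MD_ : DM_;
  const int tMIslot = corrected ? MI_ : DD_;

  for (int i = 1; i <= Lq; ++i) {
    double dMM = LOG0, dMI = LOG0, dIM = LOG0, dDG = LOG0, dGD = LOG0;
    const double qMM_ = (i >= 2) ? qtr(i - 2, MM_) : LOG0;
    const double qIM_ = (i >= 2) ? qtr(i - 2, IM_) : LOG0;
    const double qDM_ = (i >= 2) ? qtr(i - 2, DM_) : LOG0;
    const double qMD_ = (i >= 2) ? qtr(i - 2, qMDslot) : LOG0;
    const double qDD_ = (i >= 2) ? qtr(i - 2, DD_) : LOG0;
    const double qMIc = qtr(i - 1, MI_);
    const double qIIc = qtr(i - 1, II_);
    for (int j = 1; j <= Lt; ++j) {
      const double oMM = sMM[j], oMI = sMI[j], oIM = sIM[j],
                   oDG = sDG[j], oGD = sGD[j];
      double nMM, nMI, nIM, nDG, nGD;
      bool off = use_co && (co(i, j) & 0x80);
      if (off) {
        nMM = nMI = nIM = nDG = nGD = LOG0;
        bt(i, j) = (Rbyte)0x80;
      } else {
        const double tMM_ = (j >= 2) ? ttr(j - 2, MM_) : LOG0;
        const double tIM_ = (j >= 2) ? ttr(j - 2, IM_) : LOG0;
        const double tDM_ = (j >= 2) ? ttr(j - 2, DM_) : LOG0;
        const double tMD_ = (j >= 2) ? ttr(j - 2, MD_) : LOG0;
        const double tDD_ = (j >= 2) ? ttr(j - 2, DD_) : LOG0;
        double dot = 0.0;
        for (int a = 0; a < 20; ++a) dot += qf(i - 1, a) * tem(j - 1, a);
        double saa = (dot > 0.0) ? std::log2(dot) : LOG0;
        if (use_ss) saa += ssm(i - 1, j - 1);
        // MAX6 over {STOP, MM, IM, MI, GD, DG}; earliest wins ties
        double bv = 0.0;
        int pred = S_STOP;
        double c;
        c = dMM + qMM_ + tMM_; if (c > bv) { bv = c; pred = S_MM; }
        c = dIM + qIM_ + tMM_; if (c > bv) { bv = c; pred = S_IM; }
        c = dMI + qMM_ + tIM_; if (c > bv) { bv = c; pred = S_MI; }
        c = dGD + qMM_ + tDM_; if (c > bv) { bv = c; pred = S_GD; }
        c = dDG + qDM_ + tMM_; if (c > bv) { bv = c; pred = S_DG; }
        nMM = saa + bv;
        // MAX2 pairs; same-state extension wins ties
        double cm, cs;
        cm = oMM + qMM_ + ttr(j - 1, tMIslot);
        cs = oMI + qMM_ + ttr(j - 1, II_);
        const bool mi_same = !(cm > cs);
        nMI = mi_same ? cs : cm;
        cm = oMM + qMD_;
        cs = oDG + qDD_;
        const bool dg_same = !(cm > cs);
        nDG = dg_same ? cs : cm;
        cm = sMM[j - 1] + qMIc + tMM_;
        cs = sIM[j - 1] + qIIc + tMM_;
        const bool im_same = !(cm > cs);
        nIM = im_same ? cs : cm;
        cm = sMM[j - 1] + tMD_;
        cs = sGD[j - 1] + tDD_;
        const bool gd_same = !(cm > cs);
        nGD = gd_same ? cs : cm;
        bt(i, j) = (Rbyte)(pred | (gd_same << 3) | (im_same << 4) |
                           (dg_same << 5) | (mi_same << 6));
        if (nMM > best) { best = nMM; ib = i; jb = j; }
      }
      dMM = oMM; dMI = oMI; dIM = oIM; dDG = oDG; dGD = oGD;
      sMM[j] = nMM; sMI[j] = nMI; sIM[j] = nIM; sDG[j] = nDG; sGD[j] = nGD;
    }
  }
  return List::create(_["score"] = best, _["i_best"] = ib, _["j_best"] = jb,
                      _["bt"] = bt);
}

// ---------------------------------------------------------------------------
// Batched Viterbi: one query against B targets laid out in interleaved
// (lane-major) arrays, branch-free compare-select maximization per lane.
// tem_b[(j*20 + a)*B + l], ttr_b[(j*7 + s)*B + l]; targets padded with
// zero probabilities up to Ltmax (LOG0 in the log-transition array).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".viterbi_batch_cpp")]]
List viterbi_batch_cpp(NumericMatrix qf, NumericMatrix qtr,
                       NumericVector tem_b, NumericVector ttr_b,
                       int B, int Ltmax, IntegerVector lens,
                       Nullable<List> cell_off, bool corrected) {
  const int Lq = qf.nrow();
  const bool use_co = cell_off.isNotNull();
  std::vector<RawMatrix> co;
  if (use_co) {
    List col(cell_off);
    for (int l = 0; l < B; ++l) co.push_back(RawMatrix(col[l]));
  }
  std::vector<RawMatrix> bts;
  for (int l = 0; l < B; ++l) {
    RawMatrix m(Lq + 1, Ltmax + 1);
    std::fill(m.begin(), m.end(), (Rbyte)0);
    bts.push_back(m);
  }
  const int n = (Ltmax + 1) * B;
  std::vector<double> sMM(n, LOG0), sMI(n, LOG0), sIM(n, LOG0),
      sDG(n, LOG0), sGD(n, LOG0);
  std::vector<double> best(B, 0.0);
  std::vector<int> ib(B, 0), jb(B, 0);
  std::vector<double> dMM(B), dMI(B), dIM(B), dDG(B), dGD(B);
  const int qMDslot = corrected ? MD_ : DM_;
  const int tMIslot = corrected ? MI_ : DD_;
  const double* tb = tem_b.begin();
  const double* rb = ttr_b.begin();

  for (int i = 1; i <= Lq; ++i) {
    std::fill(dMM.begin(), dMM.end(), LOG0);
    std::fill(dMI.begin(), dMI.end(), LOG0);
    std::fill(dIM.begin(), dIM.end(), LOG0);
    std::fill(dDG.begin(), dDG.end(), LOG0);
    std::fill(dGD.begin(), dGD.end(), LOG0);
    const double qMM_ = (i >= 2) ? qtr(i - 2, MM_) : LOG0;
    const double qIM_ = (i >= 2) ? qtr(i - 2, IM_) : LOG0;
    const double qDM_ = (i >= 2) ? qtr(i - 2, DM_) : LOG0;
    const double qMD_ = (i >= 2) ? qtr(i - 2, qMDslot) : LOG0;
    const double qDD_ = (i >= 2) ? qtr(i - 2, DD_) : LOG0;
    const double qMIc = qtr(i - 1, MI_);
    const double qIIc = qtr(i - 1, II_);
    for (int j = 1; j <= Ltmax; ++j) {
      const int jo = j * B, jp = (j - 1) * B;
      for (int l = 0; l < B; ++l) {
        const double oMM = sMM[jo + l], oMI = sMI[jo + l], oIM = sIM[jo + l],
                     oDG = sDG[jo + l], oGD = sGD[jo + l];
        double nMM, nMI, nIM, nDG, nGD;
        const bool off = use_co && j <= lens[l] && (co[l](i, j) & 0x80);
        if (off) {
          nMM = nMI = nIM = nDG = nGD = LOG0;
          bts[l](i, j) = (Rbyte)0x80;
        } else {
          const double tMM_ = (j >= 2) ? rb[((j - 2) * 7 + MM_) * B + l] : LOG0;
          const double tIM_ = (j >= 2) ? rb[((j - 2) * 7 + IM_) * B + l] : LOG0;
          const double tDM_ = (j >= 2) ? rb[((j - 2) * 7 + DM_) * B + l] : LOG0;
          const double tMD_ = (j >= 2) ? rb[((j - 2) * 7 + MD_) * B + l] : LOG0;
          const double tDD_ = (j >= 2) ? rb[((j - 2) * 7 + DD_) * B + l] : LOG0;
          double dot = 0.0;
          const double* tcol = tb + (size_t)(j - 1) * 20 * B + l;
          for (int a = 0; a < 20; ++a) dot += qf(i - 1, a) * tcol[(size_t)a * B];
          const double saa = (dot > 0.0) ? std::log2(dot) : LOG0;
          // VMAX6: five compare-select steps, strictly-greater update
          double bv = 0.0;
          int pred = S_STOP;
          double c;
          bool gt;
          c = dMM[l] + qMM_ + tMM_; gt = c > bv; bv = gt ? c : bv; pred = gt ? S_MM : pred;
          c = dIM[l] + qIM_ + tMM_; gt = c > bv; bv = gt ? c : bv; pred = gt ? S_IM : pred;
          c = dMI[l] + qMM_ + tIM_; gt = c > bv; bv = gt ? c : bv; pred = gt ? S_MI : pred;
          c = dGD[l] + qMM_ + tDM_; gt = c > bv; bv = gt ? c : bv; pred = gt ? S_GD : pred;
          c = dDG[l] + qDM_ + tMM_; gt = c > bv; bv = gt ? c : bv; pred = gt ? S_DG : pred;
          nMM = saa + bv;
          // VMAX2: predecessor MM only when strictly greater
          double cm, cs;
          cm = oMM + qMM_ + rb[((j - 1) * 7 + tMIslot) * B + l];
          cs = oMI + qMM_ + rb[((j - 1) * 7 + II_) * B + l];
          const bool mi_same = !(cm > cs);
          nMI = mi_same ? cs : cm;
          cm = oMM + qMD_;
          cs = oDG + qDD_;
          const bool dg_same = !(cm > cs);
          nDG = dg_same ? cs : cm;
          cm = sMM[jp + l] + qMIc + tMM_;
          cs = sIM[jp + l] + qIIc + tMM_;
          const bool im_same = !(cm > cs);
          nIM = im_same ? cs : cm;
          cm = sMM[jp + l] + tMD_;
          cs = sGD[jp + l] + tDD_;
          const bool gd_same = !(cm > cs);
          nGD = gd_same ? cs : cm;
          bts[l](i, j) = (Rbyte)(pred | (gd_same << 3) | (im_same << 4) |
                                 (dg_same << 5) | (mi_same << 6));
          // lane validity mask: padded columns never update the best
          const bool upd = (j <= lens[l]) && (nMM > best[l]);
          best[l] = upd ? nMM : best[l];
          ib[l] = upd ? i : ib[l];
          jb[l] = upd ? j : jb[l];
        }
        dMM[l] = oMM; dMI[l] = oMI; dIM[l] = oIM; dDG[l] = oDG; dGD[l] = oGD;
        sMM[jo + l] = nMM; sMI[jo + l] = nMI; sIM[jo + l] = nIM;
        sDG[jo + l] = nDG; sGD[jo + l] = nGD;
      }
    }
  }
  List out(B);
  for (int l = 0; l < B; ++l) {
    out[l] = List::create(_["score"] = best[l], _["i_best"] = ib[l],
                          _["j_best"] = jb[l], _["bt"] = bts[l]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward-Backward over the same pair-state model, log2 space.
// ---------------------------------------------------------------------------

static inline double lse2(double a, double b) {
  if (a < b) { double t = a; a = b; b = t; }
  if (a <= -1e29) return LOG0F;
  const double d = b - a;
  if (d < -80.0) return a;
  return a + std::log1p(std::exp2(d)) * 1.4426950408889634;
}

// [[Rcpp::export(name = ".forward_backward_cpp")]]
List forward_backward_cpp(NumericMatrix qf, NumericMatrix qtr,
                          NumericMatrix tem, NumericMatrix ttr,
                          bool corrected) {
  const int Lq = qf.nrow(), Lt = tem.nrow();
  const int qMDslot = corrected ? MD_ : DM_;
  const int tMIslot = corrected ? MI_ : DD_;
  NumericMatrix saa(Lq, Lt);
  for (int i = 0; i < Lq; ++i) {
    for (int j = 0; j < Lt; ++j) {
      double dot = 0.0;
      for (int a = 0; a < 20; ++a) dot += qf(i, a) * tem(j, a);
      saa(i, j) = (dot > 0.0) ? std::log2(dot) : LOG0F;
    }
  }
  const int W = Lt + 1;
  auto at = [W](std::vector<double>& m, int i, int j) -> double& {
    return m[(size_t)i * W + j];
  };
  const size_t sz = (size_t)(Lq + 1) * W;
  std::vector<double> fMM(sz, LOG0F), fMI(sz, LOG0F), fIM(sz, LOG0F),
      fDG(sz, LOG0F), fGD(sz, LOG0F);
  double zf = LOG0F;
  for (int i = 1; i <= Lq; ++i) {
    const double qMM_ = (i >= 2) ? qtr(i - 2, MM_) : LOG0F;
    const double qIM_ = (i >= 2) ? qtr(i - 2, IM_) : LOG0F;
    const double qDM_ = (i >= 2) ? qtr(i - 2, DM_) : LOG0F;
    const double qMD_ = (i >= 2) ? qtr(i - 2, qMDslot) : LOG0F;
    const double qDD_ = (i >= 2) ? qtr(i - 2, DD_) : LOG0F;
    for (int j = 1; j <= Lt; ++j) {
      const double tMM_ = (j >= 2) ? ttr(j - 2, MM_) : LOG0F;
      const double tIM_ = (j >= 2) ? ttr(j - 2, IM_) : LOG0F;
      const double tDM_ = (j >= 2) ? ttr(j - 2, DM_) : LOG0F;
      const double tMD_ = (j >= 2) ? ttr(j - 2, MD_) : LOG0F;
      const double tDD_ = (j >= 2) ? ttr(j - 2, DD_) : LOG0F;
      double s = 0.0;  // local entry option
      s = lse2(s, at(fMM, i - 1, j - 1) + qMM_ + tMM_);
      s = lse2(s, at(fMI, i - 1, j - 1) + qMM_ + tIM_);
      s = lse2(s, at(fIM, i - 1, j - 1) + qIM_ + tMM_);
      s = lse2(s, at(fDG, i - 1, j - 1) + qDM_ + tMM_);
      s = lse2(s, at(fGD, i - 1, j - 1) + qMM_ + tDM_);
      at(fMM, i, j) = saa(i - 1, j - 1) + s;
      at(fMI, i, j) = lse2(at(fMM, i - 1, j) + qMM_ + ttr(j - 1, tMIslot),
                           at(fMI, i - 1, j) + qMM_ + ttr(j - 1, II_));
      at(fDG, i, j) = lse2(at(fMM, i - 1, j) + qMD_,
                           at(fDG, i - 1, j) + qDD_);
      at(fIM, i, j) = lse2(at(fMM, i, j - 1) + qtr(i - 1, MI_) + tMM_,
                           at(fIM, i, j - 1) + qtr(i - 1, II_) + tMM_);
      at(fGD, i, j) = lse2(at(fMM, i, j - 1) + tMD_,
                           at(fGD, i, j - 1) + tDD_);
      zf = lse2(zf, at(fMM, i, j));
    }
  }
  std::vector<double> bMM(sz, LOG0F), bMI(sz, LOG0F), bIM(sz, LOG0F),
      bDG(sz, LOG0F), bGD(sz, LOG0F);
  double zb = LOG0F;
  for (int i = Lq; i >= 1; --i) {
    const double qMMc = qtr(i - 1, MM_);
    const double qMIc = qtr(i - 1, MI_);
    const double qMDc = qtr(i - 1, qMDslot);
    const double qIMc = qtr(i - 1, IM_);
    const double qIIc = qtr(i - 1, II_);
    const double qDMc = qtr(i - 1, DM_);
    const double qDDc = qtr(i - 1, DD_);
    for (int j = Lt; j >= 1; --j) {
      const double tMMc = ttr(j - 1, MM_);
      const double tMIc = ttr(j - 1, tMIslot);
      const double tMDc = ttr(j - 1, MD_);
      const double tIMc = ttr(j - 1, IM_);
      const double tIIc = ttr(j - 1, II_);
      const double tDMc = ttr(j - 1, DM_);
      const double tDDc = ttr(j - 1, DD_);
      const bool di = i + 1 <= Lq, dj = j + 1 <= Lt;
      const double dsaa = (di && dj) ? saa(i, j) : LOG0F;  // S_aa(i+1, j+1)
      double s = 0.0;  // alignment may end here
      if (di && dj) s = lse2(s, at(bMM, i + 1, j + 1) + dsaa + qMMc + tMMc);
      if (di) s = lse2(s, at(bMI, i + 1, j) + qMMc + tMIc);
      if (dj) s = lse2(s, at(bIM, i, j + 1) + qMIc + tMMc);
      if (di) s = lse2(s, at(bDG, i + 1, j) + qMDc);
      if (dj) s = lse2(s, at(bGD, i, j + 1) + tMDc);
      at(bMM, i, j) = s;
      double v = LOG0F;
      if (di && dj) v = lse2(v, at(bMM, i + 1, j + 1) + dsaa + qMMc + tIMc);
      if (di) v = lse2(v, at(bMI, i + 1, j) + qMMc + tIIc);
      at(bMI, i, j) = v;
      v = LOG0F;
      if (di && dj) v = lse2(v, at(bMM, i + 1, j + 1) + dsaa + qIMc + tMMc);
      if (dj) v = lse2(v, at(bIM, i, j + 1) + qIIc + tMMc);
      at(bIM, i, j) = v;
      v = LOG0F;
      if (di && dj) v = lse2(v, at(bMM, i + 1, j + 1) + dsaa + qDMc + tMMc);
      if (di) v = lse2(v, at(bDG, i + 1, j) + qDDc);
      at(bDG, i, j) = v;
      v = LOG0F;
      if (di && dj) v = lse2(v, at(bMM, i + 1, j + 1) + dsaa + qMMc + tDMc);
      if (dj) v = lse2(v, at(bGD, i, j + 1) + tDDc);
      at(bGD, i, j) = v;
      zb = lse2(zb, saa(i - 1, j - 1) + at(bMM, i, j));
    }
  }
  NumericMatrix log_post(Lq, Lt);
  for (int i = 1; i <= Lq; ++i) {
    for (int j = 1; j <= Lt; ++j) {
      log_post(i - 1, j - 1) = at(fMM, i, j) + at(bMM, i, j) - zf;
    }
  }
  return List::create(_["log_post"] = log_post, _["log_total_f"] = zf,
                      _["log_total_b"] = zb);
}

// ---------------------------------------------------------------------------
// Maximum Accuracy decoding: three-move local DP over gains P(i,j) - mact.
// Tie order: STOP, diag, up, left (earliest wins, strictly-greater update).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mac_cpp")]]
List mac_cpp(NumericMatrix post, double mact) {
  const int Lq = post.nrow(), Lt = post.ncol();
  const int W = Lt + 1;
  std::vector<double> M((size_t)(Lq + 1) * W, 0.0);
  std::vector<unsigned char> ptr((size_t)(Lq + 1) * W, 0);
  double best = 0.0;
  int ib = 0, jb = 0;
  for (int i = 1; i <= Lq; ++i) {
    for (int j = 1; j <= Lt; ++j) {
      const double gain = post(i - 1, j - 1) - mact;
      double bv = 0.0;
      unsigned char p = 0;
      double c = M[(size_t)(i - 1) * W + (j - 1)] + gain;
      if (c > bv) { bv = c; p = 1; }
      c = M[(size_t)(i - 1) * W + j];
      if (c > bv) { bv = c; p = 2; }
      c = M[(size_t)i * W + (j - 1)];
      if (c > bv) { bv = c; p = 3; }
      M[(size_t)i * W + j] = bv;
      ptr[(size_t)i * W + j] = p;
      if (bv > best) { best = bv; ib = i; jb = j; }
    }
  }
  std::vector<int> pi, pj, pm;
  int i = ib, j = jb;
  while (i > 0 && j > 0) {
    const unsigned char p = ptr[(size_t)i * W + j];
    if (p == 0) break;
    if (p == 1) { pi.push_back(i); pj.push_back(j); pm.push_back(S_MM); --i; --j; }
    else if (p == 2) { pi.push_back(i); pj.push_back(j); pm.push_back(S_DG); --i; }
    else { pi.push_back(i); pj.push_back(j); pm.push_back(S_GD); --j; }
  }
  const int n = (int)pi.size();
  IntegerMatrix path(n, 3);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = pi[n - 1 - k];
    path(k, 1) = pj[n - 1 - k];
    path(k, 2) = pm[n - 1 - k];
  }
  return List::create(_["score"] = best, _["path"] = path);
}

// ---------------------------------------------------------------------------
// Prefilter kernels on a dense per-cell score matrix S (query columns x
// target column-state letters): best ungapped diagonal segment, and
// affine-gap Smith-Waterman.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".diag_ungapped_cpp")]]
double diag_ungapped_cpp(NumericMatrix S) {
  const int n = S.nrow(), m = S.ncol();
  double best = 0.0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    double run = 0.0;
    const int i0 = d < 0 ? -d : 0;
    const int j0 = d < 0 ? 0 : d;
    for (int i = i0, j = j0; i < n && j < m; ++i, ++j) {
      run += S(i, j);
      if (run < 0.0) run = 0.0;
      if (run > best) best = run;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_affine_cpp")]]
double sw_affine_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> H(m + 1, 0.0), E(m + 1, -1e30);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0, F = -1e30;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j] - gap_open, E[j] - gap_extend);
      F = std::max(H[j - 1] - gap_open, F - gap_extend);
      double h = diag + S(i - 1, j - 1);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
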