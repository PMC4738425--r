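#include <Rcpp.h>
using namespace Rcpp;

// Conditional gene-drop particle filter for expected pairwise IBD at one
// map position. Each particle carries phased founder alleles at the two
// flanking markers and founder-origin labels at the position; meioses are
// sampled from the Haldane-transition prior restricted to the child's
// observed flanking dosages, the restriction mass feeding the particle
// weight. Systematic resampling keeps the effective sample size healthy on
// deep pedigrees (plain sequential importance sampling degenerates).
//
// ord, sire, dam: 0-based indices, parents before offspring, -1 = founder.
// gL, gR: dosages at the flanking markers (-1 = missing / no marker).
// pL, pR: allele frequencies used for unobserved founder haplotypes.
// thetaL / thetaR: recombination fraction flank -> position -> flank
// (0.5 when a flank is absent). Returns the weighted relationship-scale
// IBD matrix with the terminal effective sample size in attribute "ess".
// [[Rcpp::export]]
NumericMatrix ibd_sample_position(IntegerVector ord, IntegerVector sire,
                                  IntegerVector dam, IntegerVector gL,
                                  IntegerVector gR, NumericVector pL,
                                  NumericVector pR, double thetaL,
                                  double thetaR, int S) {
  const int n = ord.size();
  int cSL[8], cSG[8], cSR[8];
  double prior8[8];
  {
    int k = 0;
    for (int sR = 0; sR < 2; ++sR)
      for (int sG = 0; sG < 2; ++sG)
        for (int sL = 0; sL < 2; ++sL) {
          cSL[k] = sL; cSG[k] = sG; cSR[k] = sR;
          double t1 = (sL == sG) ? 1.0 - thetaL : thetaL;
          double t2 = (sG == sR) ? 1.0 - thetaR : thetaR;
          prior8[k] = 0.5 * t1 * t2;
          ++k;
        }
  }
  // particle state, layout [S * individual + particle]
  const size_t NS = (size_t)n * S;
  std::vector<int> aL1(NS), aL2(NS), aR1(NS), aR2(NS), o1(NS), o2(NS);
  std::vector<int> bL1(NS), bL2(NS), bR1(NS), bR2(NS), p1(NS), p2(NS);
  std::vector<double> w(S, 1.0 / S);
  std::vector<int> processed;
  processed.reserve(n);
  std::vector<int> idx(S);
  std::vector<double> cw(S);

  double ess = S;
  for (int oi = 0; oi < n; ++oi) {
    const int i = ord[oi];
    const int fi = sire[i], mi = dam[i];
    const size_t base = (size_t)S * i;
    if (fi < 0 && mi < 0) {
      for (int s = 0; s < S; ++s) {
        if (gL[i] == 1) {
          int z = (unif_rand() < 0.5) ? 1 : 0;
          aL1[base + s] = z; aL2[base + s] = 1 - z;
        } else if (gL[i] >= 0) {
          aL1[base + s] = aL2[base + s] = gL[i] / 2;
        } else {
          aL1[base + s] = (unif_rand() < pL[i]) ? 1 : 0;
          aL2[base + s] = (unif_rand() < pL[i]) ? 1 : 0;
        }
        if (gR[i] == 1) {
          int z = (unif_rand() < 0.5) ? 1 : 0;
          aR1[base + s] = z; aR2[base + s] = 1 - z;
        } else if (gR[i] >= 0) {
          aR1[base + s] = aR2[base + s] = gR[i] / 2;
        } else {
          aR1[base + s] = (unif_rand() < pR[i]) ? 1 : 0;
          aR2[base + s] = (unif_rand() < pR[i]) ? 1 : 0;
        }
        o1[base + s] = 2 * i + 1;
        o2[base + s] = 2 * i + 2;
      }
      processed.push_back(i);
      continue;
    }
    const size_t fb = (size_t)S * fi, mb = (size_t)S * mi;
    double wsum = 0.0;
    for (int s = 0; s < S; ++s) {
      double wk64[64], tot = 0.0;
      const int faL[2] = {aL1[fb + s], aL2[fb + s]};
      const int faR[2] = {aR1[fb + s], aR2[fb + s]};
      const int maL[2] = {aL1[mb + s], aL2[mb + s]};
      const int maR[2] = {aR1[mb + s], aR2[mb + s]};
      for (int p = 0; p < 8; ++p) {
        const int fL = faL[cSL[p]], fR = faR[cSR[p]];
        for (int m = 0; m < 8; ++m) {
          double wk = prior8[p] * prior8[m];
          if (gL[i] >= 0 && fL + maL[cSL[m]] != gL[i]) wk = 0.0;
          else if (gR[i] >= 0 && fR + maR[cSR[m]] != gR[i]) wk = 0.0;
          wk64[p * 8 + m] = wk;
          tot += wk;
        }
      }
      if (tot <= 0.0) {
        w[s] = 0.0;
        // state for this individual is arbitrary; particle is dead
        aL1[base + s] = aR1[base + s] = 0; o1[base + s] = 2 * i + 1;
        aL2[base + s] = aR2[base + s] = 0; o2[base + s] = 2 * i + 2;
        continue;
      }
      w[s] *= tot;
      double u = unif_rand() * tot;
      int pick = 63;
      double acc = 0.0;
      for (int k = 0; k < 64; ++k) {
        acc += wk64[k];
        if (u <= acc) { pick = k; break; }
      }
      const int p = pick / 8, m = pick % 8;
      aL1[base + s] = faL[cSL[p]];
      aR1[base + s] = faR[cSR[p]];
      o1[base + s] = cSG[p] ? o2[fb + s] : o1[fb + s];
      aL2[base + s] = maL[cSL[m]];
      aR2[base + s] = maR[cSR[m]];
      o2[base + s] = cSG[m] ? o2[mb + s] : o1[mb + s];
    }
    processed.push_back(i);
    for (int s = 0; s < S; ++s) wsum += w[s];
    if (wsum <= 0.0) {
      // every particle inconsistent (possible under genotyping gaps):
      // restart weights uniformly
      for (int s = 0; s < S; ++s) w[s] = 1.0 / S;
      wsum = 1.0;
    } else {
      double w2 = 0.0;
      for (int s = 0; s < S; ++s) { w[s] /= wsum; w2 += w[s] * w[s]; }
      ess = 1.0 / w2;
      if (ess < 0.5 * S) {
        // systematic resampling over the processed sub-pedigree
        double u0 = unif_rand() / S;
        double cacc = 0.0;
        int j = 0;
        for (int s = 0; s < S; ++s) {
          const double target = u0 + (double)s / S;
          while (cacc + w[j] < target && j < S - 1) { cacc += w[j]; ++j; }
          idx[s] = j;
        }
        for (size_t t = 0; t < processed.size(); ++t) {
          const size_t pb = (size_t)S * processed[t];
          for (int s = 0; s < S; ++s) {
            const size_t from = pb + idx[s], to = pb + s;
            bL1[to] = aL1[from]; bL2[to] = aL2[from];
            bR1[to] = aR1[from]; bR2[to] = aR2[from];
            p1[to] = o1[from]; p2[to] = o2[from];
          }
          for (int s = 0; s < S; ++s) {
            const size_t to = pb + s;
            aL1[to] = bL1[to]; aL2[to] = bL2[to];
            aR1[to] = bR1[to]; aR2[to] = bR2[to];
            o1[to] = p1[to]; o2[to] = p2[to];
          }
        }
        for (int s = 0; s < S; ++s) w[s] = 1.0 / S;
        ess = S;
      }
    }
  }

  NumericMatrix ibd(n, n);
  std::vector<std::vector<int>> bucket(2 * n + 1);
  for (int s = 0; s < S; ++s) {
    if (w[s] <= 0.0) continue;
    const double ws = 0.5 * w[s];
    for (int lb = 1; lb <= 2 * n; ++lb) bucket[lb].clear();
    for (int i = 0; i < n; ++i) {
      bucket[o1[(size_t)S * i + s]].push_back(i);
      bucket[o2[(size_t)S * i + s]].push_back(i);
    }
    for (int lb = 1; lb <= 2 * n; ++lb) {
      const std::vector<int> &mbk = bucket[lb];
      for (size_t a = 0; a < mbk.size(); ++a)
        for (size_t b = 0; b < mbk.size(); ++b)
          ibd(mbk[a], mbk[b]) += ws;
    }
  }
  ibd.attr("ess") = ess;
  return ibd;
}
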