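// Marginalised likelihood and MCMC engine for the multi-species dynamic
// occupancy model.
//
// The latent yearly occurrence states Z[i,j,k] form, for each species i and
// site j, a two-state Markov chain with initial distribution (1-psi1, psi1)
// and transition probabilities P(1|1)=phi[k], P(1|0)=gamma[k]. Detections on
// the L surveys of a year are Bernoulli emissions conditional on Z. The
// likelihood sums over all latent sequences with a log-domain forward
// recursion, so no discrete state is ever sampled.
//
// State layout (species-parameter matrix `sp`, column-major, S rows):
//   col 0 psi1_0   species initial-occurrence intercepts
//   col 1 gamma_0  colonisation intercepts
//   col 2 phi_0    persistence intercepts
//   col 3 p_0      detection intercepts
//   col 4 p_2      phenology (linear date) coefficients
//   col 5 p_3      phenology (quadratic date) coefficients
// Community slope vector `comm` (17):
//   0..4  psi1_1..psi1_5 (d', restored, woody, d'xrestored, d'xwoody)
//   5..9  gamma_1..gamma_5
//   10..14 phi_1..phi_5
//   15 p_1 (degree), 16 p_4 (survey flowers)
// Year offsets: colonisation/persistence act only on transitions (years
// >= 2), so their offsets are pinned at the first transition year and free
// from year 3 on; the detection offset is pinned at year 1. Pinning a year
// that the predictor never touches would leave a likelihood-flat ridge
// against the intercept level.
// In the random-slopes variant the fifteen ecological d'-based community
// slopes are replaced by species-specific slopes `slope` (S x 6:
// psi1_r, psi1_w, gamma_r, gamma_w, phi_r, phi_w), each with its own
// hierarchical mean/sd; p_1 and p_4 are retained.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_invlogit(double x) {
  return x > 0.0 ? -log1p(exp(-x)) : x - log1p(exp(x));
}

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(exp(-fabs(a - b)));
}

// normal log-density up to the additive constant -0.5*log(2*pi)
static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - log(sd);
}

struct Occu {
  int S, J, K, L;
  const int *V;          // S x J x K x L, 0 at unobserved cells
  const int *obs;        // J x K x L survey mask (1 = conducted)
  const double *restored;      // J
  const double *woody;         // J x K (standardised)
  const double *date;          // J x K x L (standardised)
  const double *flowers;       // J x K x L (standardised)
  const double *dp;            // S (standardised d')
  const double *deg;           // S (standardised log degree)
  bool rs;

  std::vector<double> sp;      // S*6
  std::vector<double> slope;   // S*6 (random-slopes variant only)
  std::vector<double> comm;    // 17
  std::vector<double> gy, fy, py;   // K each, first element pinned at 0
  std::vector<double> hmu, hsig;    // 6 hyper pairs for sp columns
  std::vector<double> smu, ssig;    // 6 hyper pairs for slope columns

  // marginal log-likelihood of species i, summed over sites
  double sslik(int i) const {
    double dpi = dp[i], degi = deg[i];
    double aInt, aR, aW, gInt, gR, gW, fInt, fR, fW;
    if (!rs) {
      aInt = sp[i] + comm[0] * dpi;
      aR = comm[1] + comm[3] * dpi;
      aW = comm[2] + comm[4] * dpi;
      gInt = sp[S + i] + comm[5] * dpi;
      gR = comm[6] + comm[8] * dpi;
      gW = comm[7] + comm[9] * dpi;
      fInt = sp[2 * S + i] + comm[10] * dpi;
      fR = comm[11] + comm[13] * dpi;
      fW = comm[12] + comm[14] * dpi;
    } else {
      aInt = sp[i];          aR = slope[i];          aW = slope[S + i];
      gInt = sp[S + i];      gR = slope[2 * S + i];  gW = slope[3 * S + i];
      fInt = sp[2 * S + i];  fR = slope[4 * S + i];  fW = slope[5 * S + i];
    }
    double dInt = sp[3 * S + i] + comm[15] * degi;
    double p2i = sp[4 * S + i], p3i = sp[5 * S + i], p4 = comm[16];

    double tot = 0.0;
    for (int j = 0; j < J; j++) {
      double r = restored[j];
      double la1 = 0.0, la0 = 0.0;
      for (int k = 0; k < K; k++) {
        // emission log-probabilities for the surveys of year k
        double e1 = 0.0;
        bool allzero = true;
        for (int l = 0; l < L; l++) {
          int m = j + J * (k + K * l);
          if (!obs[m]) continue;
          double dt = date[m];
          double lp = dInt + p2i * dt + p3i * dt * dt + p4 * flowers[m] + py[k];
          int v = V[i + S * (j + J * (k + K * l))];
          if (v) { e1 += log_invlogit(lp); allzero = false; }
          else   { e1 += log_invlogit(-lp); }
        }
        double e0 = allzero ? 0.0 : R_NegInf;
        if (k == 0) {
          double lpsi = aInt + aR * r + aW * woody[j];
          la1 = log_invlogit(lpsi) + e1;
          la0 = log_invlogit(-lpsi) + e0;
        } else {
          double lg = gInt + gR * r + gW * woody[j + J * k] + gy[k];
          double lf = fInt + fR * r + fW * woody[j + J * (k - 1)] + fy[k];
          double n1 = lse2(la1 + log_invlogit(lf), la0 + log_invlogit(lg)) + e1;
          double n0 = lse2(la1 + log_invlogit(-lf), la0 + log_invlogit(-lg)) + e0;
          la1 = n1; la0 = n0;
        }
      }
      tot += lse2(la1, la0);
    }
    return tot;
  }
};

static void fillState(Occu &o, const List &init, bool rs) {
  NumericMatrix spI = init["sp"];
  o.sp.assign(spI.begin(), spI.end());
  NumericVector commI = init["comm"];
  o.comm.assign(commI.begin(), commI.end());
  NumericVector gyI = init["gamma_year"], fyI = init["phi_year"], pyI = init["p_year"];
  o.gy.assign(gyI.begin(), gyI.end());
  o.fy.assign(fyI.begin(), fyI.end());
  o.py.assign(pyI.begin(), pyI.end());
  NumericVector hmuI = init["hyper_mu"], hsigI = init["hyper_sigma"];
  o.hmu.assign(hmuI.begin(), hmuI.end());
  o.hsig.assign(hsigI.begin(), hsigI.end());
  if (rs) {
    NumericMatrix slI = init["slope"];
    o.slope.assign(slI.begin(), slI.end());
    NumericVector smuI = init["slope_mu"], ssigI = init["slope_sigma"];
    o.smu.assign(smuI.begin(), smuI.end());
    o.ssig.assign(ssigI.begin(), ssigI.end());
  } else {
    o.slope.assign(6 * o.S, 0.0);
    o.smu.assign(6, 0.0);
    o.ssig.assign(6, 1.0);
  }
}

static Occu makeModel(IntegerVector &V, IntegerVector &obs,
                      NumericVector &restored, NumericMatrix &woody,
                      NumericVector &date, NumericVector &flowers,
                      NumericVector &dp, NumericVector &deg,
                      IntegerVector &dims, bool rs) {
  Occu o;
  o.S = dims[0]; o.J = dims[1]; o.K = dims[2]; o.L = dims[3];
  o.V = INTEGER(V); o.obs = INTEGER(obs);
  o.restored = REAL(restored); o.woody = REAL(woody);
  o.date = REAL(date); o.flowers = REAL(flowers);
  o.dp = REAL(dp); o.deg = REAL(deg);
  o.rs = rs;
  return o;
}

// [[Rcpp::export]]
NumericVector occuLoglikCpp(IntegerVector V, IntegerVector obs,
                            NumericVector restored, NumericMatrix woody,
                            NumericVector date, NumericVector flowers,
                            NumericVector dp, NumericVector deg,
                            IntegerVector dims, List params, bool randomSlopes) {
  Occu o = makeModel(V, obs, restored, woody, date, flowers, dp, deg, dims,
                     randomSlopes);
  fillState(o, params, randomSlopes);
  NumericVector out(o.S);
  for (int i = 0; i < o.S; i++) out[i] = o.sslik(i);
  return out;
}

// [[Rcpp::export]]
List runOccuChainCpp(IntegerVector V, IntegerVector obs,
                     NumericVector restored, NumericMatrix woody,
                     NumericVector date, NumericVector flowers,
                     NumericVector dp, NumericVector deg,
                     IntegerVector dims, List init, List priors,
                     int nIter, int nWarmup, bool randomSlopes) {
  Occu o = makeModel(V, obs, restored, woody, date, flowers, dp, deg, dims,
                     randomSlopes);
  fillState(o, init, randomSlopes);
  const int S = o.S, K = o.K;
  const bool rs = randomSlopes;

  const double slopeSd = as<double>(priors["slope_sd"]);
  const double hyperMeanSd = as<double>(priors["hypermean_sd"]);
  const double hyperSdScale = as<double>(priors["hypersd_scale"]);
  const double yearSd = as<double>(priors["year_sd"]);

  std::vector<double> sll(S), cand(S);
  double tot = 0.0;
  for (int i = 0; i < S; i++) { sll[i] = o.sslik(i); tot += sll[i]; }

  // adaptive scales (log sd of random-walk proposals) and batch counters
  std::vector<double> lsSp(6 * S, log(0.5)), lsSl(6 * S, log(0.5));
  std::vector<double> lsComm(17, log(0.1)), lsYear(3 * K, log(0.1));
  std::vector<double> lsHs(6, log(0.3)), lsSs(6, log(0.3));
  std::vector<double> lsTr(4, log(0.2)), lsTrS(6, log(0.2));
  std::vector<int> acSp(6 * S, 0), acSl(6 * S, 0), acComm(17, 0),
      acYear(3 * K, 0), acHs(6, 0), acSs(6, 0), acTr(4, 0), acTrS(6, 0);
  const int batch = 50;
  int batchNum = 0;

  const int nYearFree = 2 * std::max(0, K - 2) + (K - 1);
  const int P = rs ? (12 * S + 2 + nYearFree + 24)
                   : (6 * S + 17 + nYearFree + 12);
  const int nKeep = nIter - nWarmup;
  NumericMatrix draws(nKeep, P);

  // scalar Metropolis update of a species-level parameter (likelihood slice
  // of species i only)
  auto updSpecies = [&](std::vector<double> &vec, int col, int i, double mu,
                        double sg, double &ls, int &ac) {
    double old = vec[col * S + i];
    double prop = old + exp(ls) * norm_rand();
    vec[col * S + i] = prop;
    double newll = o.sslik(i);
    double lr = newll - sll[i] + ldnorm(prop, mu, sg) - ldnorm(old, mu, sg);
    if (log(unif_rand()) < lr) {
      tot += newll - sll[i];
      sll[i] = newll;
      ac++;
    } else {
      vec[col * S + i] = old;
    }
  };

  // scalar Metropolis update of a global parameter (full likelihood)
  auto updGlobal = [&](double &x, double priorSd, double &ls, int &ac) {
    double old = x;
    double prop = old + exp(ls) * norm_rand();
    x = prop;
    double newtot = 0.0;
    for (int i = 0; i < S; i++) { cand[i] = o.sslik(i); newtot += cand[i]; }
    double lr = newtot - tot + ldnorm(prop, 0.0, priorSd) -
                ldnorm(old, 0.0, priorSd);
    if (log(unif_rand()) < lr) {
      sll = cand; tot = newtot; ac++;
    } else {
      x = old;
    }
  };

  // hyper-sd update: half-Normal prior, Metropolis on the log scale
  auto updSig = [&](double &sig, const std::vector<double> &vals, int col,
                    double mu, double &ls, int &ac) {
    double old = sig;
    double prop = old * exp(exp(ls) * norm_rand());
    double lr = 0.0;
    for (int i = 0; i < S; i++) {
      double x = vals[col * S + i];
      lr += ldnorm(x, mu, prop) - ldnorm(x, mu, old);
    }
    lr += -0.5 * (prop * prop - old * old) / (hyperSdScale * hyperSdScale);
    lr += log(prop) - log(old); // Jacobian of the log transform
    if (log(unif_rand()) < lr) { sig = prop; ac++; } else { sig = old; }
  };

  // conjugate Gibbs draw of a hypermean given intercepts and hyper-sd
  auto gibbsMu = [&](double &mu, const std::vector<double> &vals, int col,
                     double sig) {
    double sum = 0.0;
    for (int i = 0; i < S; i++) sum += vals[col * S + i];
    double prec = S / (sig * sig) + 1.0 / (hyperMeanSd * hyperMeanSd);
    double mean = (sum / (sig * sig)) / prec;
    mu = mean + norm_rand() / sqrt(prec);
  };

  for (int t = 1; t <= nIter; t++) {
    for (int i = 0; i < S; i++) {
      for (int c = 0; c < 6; c++)
        updSpecies(o.sp, c, i, o.hmu[c], o.hsig[c], lsSp[c * S + i],
                   acSp[c * S + i]);
      if (rs)
        for (int c = 0; c < 6; c++)
          updSpecies(o.slope, c, i, o.smu[c], o.ssig[c], lsSl[c * S + i],
                     acSl[c * S + i]);
    }
    if (!rs)
      for (int c = 0; c < 15; c++)
        updGlobal(o.comm[c], slopeSd, lsComm[c], acComm[c]);
    updGlobal(o.comm[15], slopeSd, lsComm[15], acComm[15]);
    updGlobal(o.comm[16], slopeSd, lsComm[16], acComm[16]);
    for (int k = 1; k < K; k++) {
      if (k >= 2) {
        updGlobal(o.gy[k], yearSd, lsYear[k], acYear[k]);
        updGlobal(o.fy[k], yearSd, lsYear[K + k], acYear[K + k]);
      }
      updGlobal(o.py[k], yearSd, lsYear[2 * K + k], acYear[2 * K + k]);
    }
    // joint translation of an intercept family and its hypermean: moves
    // along the level ridge of the centred hierarchy in one step
    for (int c = 0; c < 4; c++) {
      double delta = exp(lsTr[c]) * norm_rand();
      double muOld = o.hmu[c];
      for (int i = 0; i < S; i++) o.sp[c * S + i] += delta;
      o.hmu[c] += delta;
      double newtot = 0.0;
      for (int i = 0; i < S; i++) { cand[i] = o.sslik(i); newtot += cand[i]; }
      double lr = newtot - tot + ldnorm(o.hmu[c], 0.0, hyperMeanSd) -
                  ldnorm(muOld, 0.0, hyperMeanSd);
      if (log(unif_rand()) < lr) {
        sll = cand; tot = newtot; acTr[c]++;
      } else {
        for (int i = 0; i < S; i++) o.sp[c * S + i] -= delta;
        o.hmu[c] = muOld;
      }
    }
    if (rs)
      for (int c = 0; c < 6; c++) {
        double delta = exp(lsTrS[c]) * norm_rand();
        double muOld = o.smu[c];
        for (int i = 0; i < S; i++) o.slope[c * S + i] += delta;
        o.smu[c] += delta;
        double newtot = 0.0;
        for (int i = 0; i < S; i++) { cand[i] = o.sslik(i); newtot += cand[i]; }
        double lr = newtot - tot + ldnorm(o.smu[c], 0.0, hyperMeanSd) -
                    ldnorm(muOld, 0.0, hyperMeanSd);
        if (log(unif_rand()) < lr) {
          sll = cand; tot = newtot; acTrS[c]++;
        } else {
          for (int i = 0; i < S; i++) o.slope[c * S + i] -= delta;
          o.smu[c] = muOld;
        }
      }
    for (int c = 0; c < 6; c++) {
      gibbsMu(o.hmu[c], o.sp, c, o.hsig[c]);
      updSig(o.hsig[c], o.sp, c, o.hmu[c], lsHs[c], acHs[c]);
    }
    if (rs)
      for (int c = 0; c < 6; c++) {
        gibbsMu(o.smu[c], o.slope, c, o.ssig[c]);
        updSig(o.ssig[c], o.slope, c, o.smu[c], lsSs[c], acSs[c]);
      }

    if (t <= nWarmup && t % batch == 0) {
      batchNum++;
      double d = std::min(0.1, 1.0 / sqrt((double)batchNum));
      auto adapt = [&](std::vector<double> &ls, std::vector<int> &ac) {
        for (size_t q = 0; q < ls.size(); q++) {
          ls[q] += (ac[q] > 0.44 * batch) ? d : -d;
          ac[q] = 0;
        }
      };
      adapt(lsSp, acSp); adapt(lsComm, acComm); adapt(lsYear, acYear);
      adapt(lsHs, acHs); adapt(lsTr, acTr);
      if (rs) { adapt(lsSl, acSl); adapt(lsSs, acSs); adapt(lsTrS, acTrS); }
    }

    if (t > nWarmup) {
      int row = t - nWarmup - 1, c = 0;
      for (size_t q = 0; q < o.sp.size(); q++) draws(row, c++) = o.sp[q];
      if (rs)
        for (size_t q = 0; q < o.slope.size(); q++) draws(row, c++) = o.slope[q];
      if (rs) {
        draws(row, c++) = o.comm[15];
        draws(row, c++) = o.comm[16];
      } else {
        for (int q = 0; q < 17; q++) draws(row, c++) = o.comm[q];
      }
      for (int k = 2; k < K; k++) draws(row, c++) = o.gy[k];
      for (int k = 2; k < K; k++) draws(row, c++) = o.fy[k];
      for (int k = 1; k < K; k++) draws(row, c++) = o.py[k];
      for (int q = 0; q < 6; q++) draws(row, c++) = o.hmu[q];
      for (int q = 0; q < 6; q++) draws(row, c++) = o.hsig[q];
      if (rs) {
        for (int q = 0; q < 6; q++) draws(row, c++) = o.smu[q];
        for (int q = 0; q < 6; q++) draws(row, c++) = o.ssig[q];
      }
    }
    if (t % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["loglik"] = tot);
}
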