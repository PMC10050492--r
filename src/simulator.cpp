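// Spiking ring-attractor network integrator.
//
// Leaky integrate-and-fire principal cells (E) and interneurons (I) on a
// ring, coupled through conductance synapses: E->I NMDA (second-order
// gating with voltage-dependent Mg block, optionally mixed with fast
// AMPA), I->E and I->I GABA-A (first-order gating). The smooth part of
// the system is advanced with Heun's second-order Runge-Kutta scheme;
// spike-triggered gating increments are applied between steps and the
// Ornstein-Uhlenbeck noise current is updated once per step with its
// exact exponential discretization and held constant within the step.
//
// The synaptic drive sums (matrix-vector products with the circulant
// weight matrices) can be evaluated either densely or, when both
// populations sit on commensurate power-of-two grids, by circular
// convolution via FFT. The two paths agree to rounding error.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------
// deterministic, platform-independent RNG (xoshiro256++ seeded via
// splitmix64) with polar-method Gaussians
// ---------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------
// iterative radix-2 complex FFT with cached plans
// ---------------------------------------------------------------------
typedef std::complex<double> cplx;

struct FftPlan {
  int n = 0;
  std::vector<int> rev;
  // contiguous twiddle tables per stage: for stage `len`, entries
  // exp(-2*pi*i*j/len), j = 0 .. len/2-1, stored as interleaved re/im
  std::vector<std::vector<double>> twr, twi;

  void init(int n_) {
    n = n_;
    rev.assign(n, 0);
    int lg = 0;
    while ((1 << lg) < n) ++lg;
    for (int i = 0; i < n; ++i)
      rev[i] = (rev[i >> 1] >> 1) | ((i & 1) << (lg - 1));
    twr.assign(lg + 1, {});
    twi.assign(lg + 1, {});
    for (int s = 1; s <= lg; ++s) {
      int len = 1 << s;
      twr[s].resize(len / 2);
      twi[s].resize(len / 2);
      for (int j = 0; j < len / 2; ++j) {
        double a = -2.0 * M_PI * j / len;
        twr[s][j] = std::cos(a);
        twi[s][j] = std::sin(a);
      }
    }
  }
  // in-place forward transform on split re/im arrays
  void fwd(double* re, double* im) const {
    for (int i = 0; i < n; ++i)
      if (i < rev[i]) {
        std::swap(re[i], re[rev[i]]);
        std::swap(im[i], im[rev[i]]);
      }
    int s = 1;
    for (int len = 2; len <= n; len <<= 1, ++s) {
      const int half = len / 2;
      const double* wr = twr[s].data();
      const double* wi = twi[s].data();
      for (int i = 0; i < n; i += len) {
        double* reA = re + i; double* imA = im + i;
        double* reB = re + i + half; double* imB = im + i + half;
        for (int j = 0; j < half; ++j) {
          double vr = reB[j] * wr[j] - imB[j] * wi[j];
          double vi = reB[j] * wi[j] + imB[j] * wr[j];
          double ur = reA[j], ui = imA[j];
          reA[j] = ur + vr; imA[j] = ui + vi;
          reB[j] = ur - vr; imB[j] = ui - vi;
        }
      }
    }
  }
  // in-place inverse transform (with 1/n scaling)
  void inv(double* re, double* im) const {
    for (int i = 0; i < n; ++i) im[i] = -im[i];
    fwd(re, im);
    double sc = 1.0 / n;
    for (int i = 0; i < n; ++i) { re[i] *= sc; im[i] *= -sc; }
  }
};

static bool is_pow2(int n) { return n > 0 && (n & (n - 1)) == 0; }

// ---------------------------------------------------------------------
// exported small pieces (documented on the R side)
// ---------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector mg_block_cpp(NumericVector V_m, double Mg) {
  int n = V_m.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = 1.0 / (1.0 + Mg * std::exp(-0.062 * V_m[i]) / 3.57);
  return out;
}

// Exact-discretization Ornstein-Uhlenbeck path: x_{k+1} =
// x_k exp(-dt/tau) + sd_stat sqrt(1 - exp(-2 dt/tau)) N(0,1).
// [[Rcpp::export]]
NumericVector ou_path_cpp(int n_steps, double dt, double tau,
                          double sd_stat, double init, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  NumericVector out(n_steps + 1);
  double a = std::exp(-dt / tau);
  double b = sd_stat * std::sqrt(1.0 - a * a);
  double x = init;
  out[0] = x;
  for (int k = 1; k <= n_steps; ++k) {
    x = a * x + (sd_stat > 0 ? b * rng.norm() : 0.0);
    out[k] = x;
  }
  return out;
}

// NMDA gating trajectory for a given presynaptic spike train, integrated
// with the same Heun scheme and spike handling as the full network.
// Returns columns t, x, S.
// [[Rcpp::export]]
NumericMatrix nmda_gating_trace_cpp(NumericVector spike_times, double t_max,
                                    double dt, double tau_nmda, double alpha,
                                    double tau_x) {
  int n_steps = static_cast<int>(std::round(t_max / dt));
  NumericMatrix out(n_steps + 1, 3);
  double x = 0.0, S = 0.0;
  int next_spike = 0;
  out(0, 0) = 0.0; out(0, 1) = x; out(0, 2) = S;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    // spikes recorded at times <= t increment x before the step
    while (next_spike < spike_times.size() &&
           spike_times[next_spike] <= t + 1e-12) {
      x += 1.0; ++next_spike;
    }
    double dx0 = -x / tau_x;
    double dS0 = -S / tau_nmda + alpha * x * (1.0 - S);
    double xp = x + dt * dx0;
    double Sp = S + dt * dS0;
    double dx1 = -xp / tau_x;
    double dS1 = -Sp / tau_nmda + alpha * xp * (1.0 - Sp);
    x += 0.5 * dt * (dx0 + dx1);
    S += 0.5 * dt * (dS0 + dS1);
    out(k + 1, 0) = t + dt; out(k + 1, 1) = x; out(k + 1, 2) = S;
  }
  return out;
}

// ---------------------------------------------------------------------
// full network simulation
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_network_cpp(List args) {
  // --- sizes, integration
  const int n_E = as<int>(args["n_E"]);
  const int n_I = as<int>(args["n_I"]);
  const double dt = as<double>(args["dt"]);
  const int n_steps = as<int>(args["n_steps"]);
  const int rec_every = as<int>(args["record_every"]);
  const bool conv = as<bool>(args["use_conv"]);

  // --- connectivity
  NumericMatrix W_EI, W_IE, W_II, W_EE;
  std::vector<double> kEI, kIE, kEE, kII;
  const bool ee_on = as<bool>(args["ee_enabled"]);
  const bool ii_uniform = as<bool>(args["ii_uniform"]);
  if (conv) {
    kEI = as<std::vector<double>>(args["kEI"]);
    kIE = as<std::vector<double>>(args["kIE"]);
    if (ee_on) kEE = as<std::vector<double>>(args["kEE"]);
    if (!ii_uniform) kII = as<std::vector<double>>(args["kII"]);
  } else {
    W_EI = as<NumericMatrix>(args["W_EI"]);
    W_IE = as<NumericMatrix>(args["W_IE"]);
    W_II = as<NumericMatrix>(args["W_II"]);
    if (ee_on) W_EE = as<NumericMatrix>(args["W_EE"]);
    if (W_EI.nrow() != n_I || W_EI.ncol() != n_E ||
        W_IE.nrow() != n_E || W_IE.ncol() != n_I)
      stop("connectivity matrices do not match the network size");
  }

  // --- membranes
  // Membrane capacitances arrive in nF; with conductances in nS, voltages
  // in mV and currents in pA, dV/dt in mV/ms equals (pA sum) / (C in pF).
  const double Cm_E = as<double>(args["Cm_E"]) * 1000.0,
               gL_E = as<double>(args["gL_E"]);
  const double VL_E = as<double>(args["VL_E"]), Vth_E = as<double>(args["Vth_E"]);
  const double Vre_E = as<double>(args["Vreset_E"]);
  const double tref_E = as<double>(args["tauref_E"]);
  const double Cm_I = as<double>(args["Cm_I"]) * 1000.0,
               gL_I = as<double>(args["gL_I"]);
  const double VL_I = as<double>(args["VL_I"]), Vth_I = as<double>(args["Vth_I"]);
  const double Vre_I = as<double>(args["Vreset_I"]);
  const double tref_I = as<double>(args["tauref_I"]);

  // --- synapses
  const double gNMDA = as<double>(args["g_NMDA_EI"]);
  const double gGABA_IE = as<double>(args["g_GABA_IE"]);
  const double gGABA_II = as<double>(args["g_GABA_II"]);
  const double gNMDA_EE = as<double>(args["g_NMDA_EE"]);
  const double gAMPA = as<double>(args["g_AMPA_EI"]);
  const double VErev = as<double>(args["V_E"]);
  const double VIrev = as<double>(args["V_I"]);
  const double Mg = as<double>(args["Mg"]);
  const double tauN = as<double>(args["tau_NMDA"]);
  const double alphaN = as<double>(args["alpha_NMDA"]);
  const double taux = as<double>(args["tau_x"]);
  const double tauG = as<double>(args["tau_GABA"]);
  const double tauA = as<double>(args["tau_AMPA"]);
  const double frA = as<double>(args["ampa_fraction"]);

  // --- external input
  const double IbackE = as<double>(args["I_back_E"]);
  const double IbackI = as<double>(args["I_back_I"]);
  const double IMS0 = as<double>(args["I_MS0"]);
  const double Aamp = as<double>(args["A"]);
  const double fMS = as<double>(args["f_MS"]);
  const double tauNoise = as<double>(args["tau_noise"]);
  const double sdStat = as<double>(args["noise_sd_stat"]);
  const bool noise_on = sdStat > 0;
  const bool poisson = as<bool>(args["poisson_mode"]);
  const double poisRate = as<double>(args["poisson_rate_ms"]);  // events/ms
  const double tauPE = as<double>(args["tau_poisson_exc"]);
  const double tauPI = as<double>(args["tau_poisson_inh"]);
  const double wPexcE = as<double>(args["w_pois_exc_E"]);
  const double wPexcI = as<double>(args["w_pois_exc_I"]);
  const double wPinhI = as<double>(args["w_pois_inh_I"]);

  // --- protocol currents
  const double cueAmp = as<double>(args["cue_amp"]);
  const double cueToff = as<double>(args["cue_t_off"]);
  const LogicalVector cueMask = args["cue_mask_E"];
  const double supAmp = as<double>(args["sup_amp"]);
  const LogicalVector supMask = args["sup_mask_I"];

  // --- initial conditions, seed
  const int vmInitMode = as<int>(args["vm_init_mode"]);  // 0 fixed, 1 unif
  const double vmFixed = as<double>(args["vm_fixed"]);
  const double vmLo = as<double>(args["vm_lo"]);
  const double vmHi = as<double>(args["vm_hi"]);
  Rng rng(static_cast<uint64_t>(as<double>(args["seed"])));

  // --- recording
  const IntegerVector idxVmE = args["idx_vm_E"];  // 0-based
  const IntegerVector idxVmI = args["idx_vm_I"];
  const int n_samp = (n_steps - 1) / rec_every + 1;

  // --- state
  std::vector<double> VE(n_E), VI(n_I);
  std::vector<double> S(n_E, 0.0), X(n_E, 0.0), SA(n_E, 0.0);
  std::vector<double> SG(n_I, 0.0);
  std::vector<double> refE(n_E, 0.0), refI(n_I, 0.0);
  std::vector<double> noiseE(n_E, 0.0), noiseI(n_I, 0.0);
  std::vector<double> peE(n_E, 0.0), peI(n_I, 0.0), piI(n_I, 0.0);

  for (int i = 0; i < n_E; ++i)
    VE[i] = (vmInitMode == 0) ? vmFixed : vmLo + (vmHi - vmLo) * rng.unif();
  for (int i = 0; i < n_I; ++i)
    VI[i] = (vmInitMode == 0) ? vmFixed : vmLo + (vmHi - vmLo) * rng.unif();

  // --- FFT plans and kernel spectra (convolution path)
  // All coupling kernels are real and even in the circular index
  // distance, so their spectra are real; storing only the real part makes
  // the per-step spectral multiplications purely real as well.
  FftPlan planE, planI;
  std::vector<double> KEI, KIE, KEE, KII;
  std::vector<double> bre, bim, cre, cim, iIre, iIim;
  int rEI = 0;
  auto real_spectrum = [](const FftPlan& plan,
                          const std::vector<double>& k) {
    std::vector<double> re(k), im(k.size(), 0.0);
    plan.fwd(re.data(), im.data());
    return re;
  };
  if (conv) {
    if (!is_pow2(n_E) || !is_pow2(n_I) || n_E % n_I != 0)
      stop("convolution coupling requires commensurate power-of-two rings");
    rEI = n_E / n_I;
    planE.init(n_E);
    planI.init(n_I);
    bre.resize(n_E); bim.resize(n_E); cre.resize(n_E); cim.resize(n_E);
    iIre.resize(n_I); iIim.resize(n_I);
    KEI = real_spectrum(planE, kEI);
    KIE = real_spectrum(planE, kIE);
    if (ee_on) KEE = real_spectrum(planE, kEE);
    if (!ii_uniform) KII = real_spectrum(planI, kII);
  }

  // drive sums
  std::vector<double> sumNMDA0(n_I), sumNMDA1(n_I);     // E->I, per I
  std::vector<double> sumGABA_E0(n_E);                  // I->E, per E
  std::vector<double> sumGABA_I0(n_I);                  // I->I, per I
  std::vector<double> sumEE0(n_E), sumEE1(n_E);         // E->E, per E
  std::vector<double> sumAMPA0(n_I);                    // AMPA E->I, per I
  std::vector<double> Sp(n_E), Xp(n_E);

  // Computes every drive sum needed by the two Heun stages. Requires S,
  // Sp (NMDA open fractions at the step start and Euler predictor), SG
  // and SA. In the convolution path the two real NMDA sequences share one
  // complex transform (S in the real slot, Sp in the imaginary slot); the
  // GABA and AMPA predictor sums are exact rescalings of the stage-1 sums
  // because those gatings decay purely exponentially between spikes.
  auto compute_drive_sums = [&]() {
    if (conv) {
      std::copy(S.begin(), S.end(), bre.begin());
      std::copy(Sp.begin(), Sp.end(), bim.begin());
      planE.fwd(bre.data(), bim.data());
      for (int q = 0; q < n_E; ++q) {
        cre[q] = bre[q] * KEI[q];
        cim[q] = bim[q] * KEI[q];
      }
      planE.inv(cre.data(), cim.data());
      for (int i = 0; i < n_I; ++i) {
        sumNMDA0[i] = cre[i * rEI];
        sumNMDA1[i] = cim[i * rEI];
      }
      if (ee_on) {
        for (int q = 0; q < n_E; ++q) {
          cre[q] = bre[q] * KEE[q];
          cim[q] = bim[q] * KEE[q];
        }
        planE.inv(cre.data(), cim.data());
        for (int i = 0; i < n_E; ++i) {
          // subtract the autapse term (diagonal removed from W_EE)
          sumEE0[i] = cre[i] - kEE[0] * S[i];
          sumEE1[i] = cim[i] - kEE[0] * Sp[i];
        }
      }
      if (frA > 0) {
        std::copy(SA.begin(), SA.end(), cre.begin());
        std::fill(cim.begin(), cim.end(), 0.0);
        planE.fwd(cre.data(), cim.data());
        for (int q = 0; q < n_E; ++q) {
          cre[q] *= KEI[q];
          cim[q] *= KEI[q];
        }
        planE.inv(cre.data(), cim.data());
        for (int i = 0; i < n_I; ++i) sumAMPA0[i] = cre[i * rEI];
      }
      // I->E: upsampled S_GABA convolved with the fine I->E kernel; the
      // length-n_E spectrum of the upsampled train is the length-n_I
      // spectrum tiled rEI times.
      std::copy(SG.begin(), SG.end(), iIre.begin());
      std::fill(iIim.begin(), iIim.end(), 0.0);
      planI.fwd(iIre.data(), iIim.data());
      for (int q = 0; q < n_E; ++q) {
        int qq = q % n_I;
        cre[q] = iIre[qq] * KIE[q];
        cim[q] = iIim[qq] * KIE[q];
      }
      planE.inv(cre.data(), cim.data());
      for (int i = 0; i < n_E; ++i) sumGABA_E0[i] = cre[i];
      if (ii_uniform) {
        double s = 0.0;
        for (int i = 0; i < n_I; ++i) s += SG[i];
        for (int i = 0; i < n_I; ++i) sumGABA_I0[i] = s;
      } else {
        for (int q = 0; q < n_I; ++q) {
          iIre[q] *= KII[q];
          iIim[q] *= KII[q];
        }
        planI.inv(iIre.data(), iIim.data());
        for (int i = 0; i < n_I; ++i) sumGABA_I0[i] = iIre[i];
      }
    } else {
      for (int i = 0; i < n_I; ++i) {
        double a0 = 0.0, a1 = 0.0;
        for (int j = 0; j < n_E; ++j) {
          a0 += W_EI(i, j) * S[j];
          a1 += W_EI(i, j) * Sp[j];
        }
        sumNMDA0[i] = a0;
        sumNMDA1[i] = a1;
      }
      for (int i = 0; i < n_E; ++i) {
        double a = 0.0;
        for (int j = 0; j < n_I; ++j) a += W_IE(i, j) * SG[j];
        sumGABA_E0[i] = a;
      }
      for (int i = 0; i < n_I; ++i) {
        double a = 0.0;
        for (int j = 0; j < n_I; ++j) a += W_II(i, j) * SG[j];
        sumGABA_I0[i] = a;
      }
      if (ee_on) {
        for (int i = 0; i < n_E; ++i) {
          double a0 = 0.0, a1 = 0.0;
          for (int j = 0; j < n_E; ++j) {
            a0 += W_EE(i, j) * S[j];
            a1 += W_EE(i, j) * Sp[j];
          }
          sumEE0[i] = a0;
          sumEE1[i] = a1;
        }
      }
      if (frA > 0) {
        for (int i = 0; i < n_I; ++i) {
          double a = 0.0;
          for (int j = 0; j < n_E; ++j) a += W_EI(i, j) * SA[j];
          sumAMPA0[i] = a;
        }
      }
    }
  };

  auto mgb = [&](double V) {
    return 1.0 / (1.0 + Mg * std::exp(-0.062 * V) / 3.57);
  };

  // OU constants
  const double ouA = std::exp(-dt / tauNoise);
  const double ouB = sdStat * std::sqrt(1.0 - ouA * ouA);
  // Poisson filter decay
  const double peDecay = std::exp(-dt / tauPE);
  const double piDecay = std::exp(-dt / tauPI);
  const double pEvent = poisRate * dt;  // P(event per step), << 1
  // GABA/AMPA predictor rescaling
  const double gabaPred = 1.0 - dt / tauG;
  const double ampaPred = 1.0 - dt / tauA;

  // --- outputs
  std::vector<double> spkTE, spkTI;
  std::vector<int> spkIdE, spkIdI;
  spkTE.reserve(1 << 16); spkTI.reserve(1 << 17);
  spkIdE.reserve(1 << 16); spkIdI.reserve(1 << 17);

  NumericVector t_samp(n_samp);
  NumericMatrix vmE(n_samp, idxVmE.size()), vmI(n_samp, idxVmI.size());
  NumericMatrix igabaE(n_samp, n_E), inmdaI(n_samp, n_I);
  NumericMatrix meanCur(n_samp, 8);
  colnames(meanCur) = CharacterVector::create(
      "I_gaba_E", "I_ext_E", "I_tot_E",
      "I_nmda_I", "I_gaba_I", "I_ext_I", "I_tot_I", "I_MS");
  double sMin = 0.0, sMax = 0.0;

  std::vector<double> dVE0(n_E), dVI0(n_I), dS0(n_E), dX0(n_E);
  std::vector<double> IextE(n_E), IextI(n_I);
  std::vector<double> VEp(n_E), VIp(n_I);

  int sampIdx = 0;
  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // ---- noise / stochastic input update (held constant within step)
    if (poisson) {
      for (int i = 0; i < n_E; ++i) {
        peE[i] *= peDecay;
        if (rng.unif() < pEvent) peE[i] += 1.0;
      }
      for (int i = 0; i < n_I; ++i) {
        peI[i] *= peDecay;
        if (rng.unif() < pEvent) peI[i] += 1.0;
        piI[i] *= piDecay;
        if (rng.unif() < pEvent) piI[i] += 1.0;
      }
    }
    if (noise_on) {
      for (int i = 0; i < n_E; ++i) noiseE[i] = ouA * noiseE[i] + ouB * rng.norm();
      for (int i = 0; i < n_I; ++i) noiseI[i] = ouA * noiseI[i] + ouB * rng.norm();
    }

    // ---- external currents at stage times
    const double IMS_t0 = poisson ? 0.0 :
      (IMS0 + (Aamp > 0 ? Aamp * std::cos(2.0 * M_PI * fMS * t / 1000.0) : 0.0));
    const double IMS_t1 = poisson ? 0.0 :
      (IMS0 + (Aamp > 0 ? Aamp * std::cos(2.0 * M_PI * fMS * (t + dt) / 1000.0) : 0.0));
    const bool cue0 = (cueAmp != 0.0) && (t < cueToff);
    const bool cue1 = (cueAmp != 0.0) && (t + dt < cueToff);

    for (int i = 0; i < n_E; ++i) {
      double base = poisson ? wPexcE * peE[i] : IbackE;
      IextE[i] = base + noiseE[i];
      if (cue0 && cueMask[i]) IextE[i] += cueAmp;
    }
    for (int i = 0; i < n_I; ++i) {
      double base = poisson ? (wPexcI * peI[i] - wPinhI * piI[i]) : IbackI;
      IextI[i] = base + IMS_t0 + noiseI[i];
      if (supAmp != 0.0 && supMask[i]) IextI[i] += supAmp;
    }

    // ---- gating derivatives and Euler predictors (local, needed by
    // both stages' drive sums)
    for (int i = 0; i < n_E; ++i) {
      dX0[i] = -X[i] / taux;
      dS0[i] = -S[i] / tauN + alphaN * X[i] * (1.0 - S[i]);
      Xp[i] = X[i] + dt * dX0[i];
      Sp[i] = S[i] + dt * dS0[i];
    }

    // ---- synaptic drive sums for both stages
    compute_drive_sums();

    // record at step start (state at time t)
    if (step % rec_every == 0) {
      t_samp[sampIdx] = t;
      double mIgE = 0, mIeE = 0, mInI = 0, mIgI = 0, mIeI = 0;
      for (int i = 0; i < n_E; ++i) {
        double ig = gGABA_IE * (VE[i] - VIrev) * sumGABA_E0[i];
        igabaE(sampIdx, i) = ig;
        mIgE += ig; mIeE += IextE[i];
      }
      for (int i = 0; i < n_I; ++i) {
        double inm = (1.0 - frA) * gNMDA * (VI[i] - VErev) * mgb(VI[i]) * sumNMDA0[i];
        inmdaI(sampIdx, i) = inm;
        mInI += inm;
        double igI = gGABA_II * (VI[i] - VIrev) * sumGABA_I0[i];
        mIgI += igI; mIeI += IextI[i];
      }
      mIgE /= n_E; mIeE /= n_E; mInI /= n_I; mIgI /= n_I; mIeI /= n_I;
      meanCur(sampIdx, 0) = mIgE;
      meanCur(sampIdx, 1) = mIeE;
      meanCur(sampIdx, 2) = mIeE - mIgE;
      meanCur(sampIdx, 3) = mInI;
      meanCur(sampIdx, 4) = mIgI;
      meanCur(sampIdx, 5) = mIeI;
      meanCur(sampIdx, 6) = mIeI - mInI - mIgI;
      meanCur(sampIdx, 7) = IMS_t0;
      for (int k = 0; k < idxVmE.size(); ++k) vmE(sampIdx, k) = VE[idxVmE[k]];
      for (int k = 0; k < idxVmI.size(); ++k) vmI(sampIdx, k) = VI[idxVmI[k]];
      ++sampIdx;
    }

    // stage-1 derivatives
    for (int i = 0; i < n_E; ++i) {
      if (refE[i] > 1e-12) { dVE0[i] = 0.0; continue; }
      double Isyn = gGABA_IE * (VE[i] - VIrev) * sumGABA_E0[i];
      if (ee_on)
        Isyn += gNMDA_EE * (VE[i] - VErev) * mgb(VE[i]) * sumEE0[i];
      dVE0[i] = (-gL_E * (VE[i] - VL_E) - Isyn + IextE[i]) / Cm_E;
    }
    for (int i = 0; i < n_I; ++i) {
      if (refI[i] > 1e-12) { dVI0[i] = 0.0; continue; }
      double Isyn = (1.0 - frA) * gNMDA * (VI[i] - VErev) * mgb(VI[i]) * sumNMDA0[i]
                  + gGABA_II * (VI[i] - VIrev) * sumGABA_I0[i];
      if (frA > 0)
        Isyn += frA * gAMPA * (VI[i] - VErev) * sumAMPA0[i];
      dVI0[i] = (-gL_I * (VI[i] - VL_I) - Isyn + IextI[i]) / Cm_I;
    }

    // predictor membrane potentials
    for (int i = 0; i < n_E; ++i)
      VEp[i] = (refE[i] > 1e-12) ? VE[i] : VE[i] + dt * dVE0[i];
    for (int i = 0; i < n_I; ++i)
      VIp[i] = (refI[i] > 1e-12) ? VI[i] : VI[i] + dt * dVI0[i];

    // ---- stage 2
    for (int i = 0; i < n_E; ++i) {
      if (refE[i] > 1e-12) continue;
      double IextE1 = IextE[i];
      if (cue0 != cue1 && cueMask[i]) IextE1 += (cue1 ? cueAmp : -cueAmp);
      double Isyn = gGABA_IE * (VEp[i] - VIrev) * (gabaPred * sumGABA_E0[i]);
      if (ee_on)
        Isyn += gNMDA_EE * (VEp[i] - VErev) * mgb(VEp[i]) * sumEE1[i];
      double dV1 = (-gL_E * (VEp[i] - VL_E) - Isyn + IextE1) / Cm_E;
      VE[i] += 0.5 * dt * (dVE0[i] + dV1);
    }
    for (int i = 0; i < n_I; ++i) {
      if (refI[i] > 1e-12) continue;
      double IextI1 = IextI[i] - IMS_t0 + IMS_t1;
      double Isyn = (1.0 - frA) * gNMDA * (VIp[i] - VErev) * mgb(VIp[i]) * sumNMDA1[i]
                  + gGABA_II * (VIp[i] - VIrev) * (gabaPred * sumGABA_I0[i]);
      if (frA > 0)
        Isyn += frA * gAMPA * (VIp[i] - VErev) * (ampaPred * sumAMPA0[i]);
      double dV1 = (-gL_I * (VIp[i] - VL_I) - Isyn + IextI1) / Cm_I;
      VI[i] += 0.5 * dt * (dVI0[i] + dV1);
    }
    // Exponentially decaying gating variables of long-quiet neurons
    // would reach the denormal range and poison the FFTs with slow
    // arithmetic; values this far below any dynamical scale are flushed
    // to zero (identically in both coupling paths).
    const double tiny = 1e-30;
    for (int i = 0; i < n_E; ++i) {
      double dX1 = -Xp[i] / taux;
      double dS1 = -Sp[i] / tauN + alphaN * Xp[i] * (1.0 - Sp[i]);
      X[i] += 0.5 * dt * (dX0[i] + dX1);
      S[i] += 0.5 * dt * (dS0[i] + dS1);
      if (X[i] < tiny) X[i] = 0.0;
      if (S[i] < tiny) S[i] = 0.0;
      if (S[i] < sMin) sMin = S[i];
      if (S[i] > sMax) sMax = S[i];
    }
    // Heun update of the purely exponential gating decays
    {
      const double heunG = 1.0 - dt / tauG + 0.5 * (dt / tauG) * (dt / tauG);
      for (int i = 0; i < n_I; ++i) {
        SG[i] *= heunG;
        if (SG[i] < tiny) SG[i] = 0.0;
      }
      if (frA > 0) {
        const double heunA = 1.0 - dt / tauA + 0.5 * (dt / tauA) * (dt / tauA);
        for (int i = 0; i < n_E; ++i) {
          SA[i] *= heunA;
          if (SA[i] < tiny) SA[i] = 0.0;
        }
      }
    }

    // ---- refractory countdown, threshold and reset
    for (int i = 0; i < n_E; ++i) {
      if (refE[i] > 1e-12) {
        refE[i] -= dt;
        if (refE[i] < 1e-12) refE[i] = 0.0;
        VE[i] = Vre_E;
      } else if (VE[i] >= Vth_E) {
        spkTE.push_back(t + dt);
        spkIdE.push_back(i);
        VE[i] = Vre_E;
        refE[i] = tref_E;
        X[i] += 1.0;  // presynaptic NMDA kick, seen from the next step on
        if (frA > 0) SA[i] += 1.0;
      }
    }
    for (int i = 0; i < n_I; ++i) {
      if (refI[i] > 1e-12) {
        refI[i] -= dt;
        if (refI[i] < 1e-12) refI[i] = 0.0;
        VI[i] = Vre_I;
      } else if (VI[i] >= Vth_I) {
        spkTI.push_back(t + dt);
        spkIdI.push_back(i);
        VI[i] = Vre_I;
        refI[i] = tref_I;
        SG[i] += 1.0;
      }
    }

    if ((step & 4095) == 0) {
      if (!std::isfinite(VE[0]) || !std::isfinite(VI[0]))
        stop("non-finite membrane potential at t = %f ms", t);
      Rcpp::checkUserInterrupt();
    }
  }

  return List::create(
    _["spike_t_E"] = wrap(spkTE), _["spike_id_E"] = wrap(spkIdE),
    _["spike_t_I"] = wrap(spkTI), _["spike_id_I"] = wrap(spkIdI),
    _["t_ms"] = t_samp,
    _["vm_E"] = vmE, _["vm_I"] = vmI,
    _["igaba_E"] = igabaE, _["inmda_I"] = inmdaI,
    _["mean_currents"] = meanCur,
    _["s_nmda_min"] = sMin, _["s_nmda_max"] = sMax);
}
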