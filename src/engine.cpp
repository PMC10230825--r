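// Stochastic population-level immune engine.
//
// State layout: [scalar populations | cytokines (16 mediators x 3 compartments) |
// clonal naive pools (CD4, CD8, B; n_clones each)].  All stochastic transitions
// are binomial thinnings / influxes drawn from R's RNG, so trajectories are
// reproducible under set.seed() on the R side.
#include <Rcpp.h>
using namespace Rcpp;

// mediators
enum Cyt { IL1, IL2, IL4, IL5, IL6, IL10, IL12, IL13, IL17, IL21, IL22, IL23,
           TNFA, TNFB, IFNG, TGFB, NCYT };
enum Comp { LYM, BLOOD, CNS, NCOMP };

// scalar populations / fields
enum St {
  DC_REST, DC_ACT, MAC_REST, MAC_ACT,
  TH1_LYM, TH2_LYM, TH17_LYM, TREG_LYM, CD8A_LYM,
  BACT_LYM, BMEM_LYM, BPLA_LYM, IGG_LYM,
  CD4_BLOOD, CD8_BLOOD, B_BLOOD, NEUT_BLOOD,
  TH1_CNS, TH17_CNS, CD8A_CNS, MAC_CNS, NEUT_CNS,
  TN_CNS, BN_CNS, BACT_CNS, BPLA_CNS, IGG_CNS,
  MICRO_REST, MICRO_ACT, ASTRO_REST, ASTRO_ACT,
  ODC, BBB, MBP, DRUG_LEVEL, NSCALAR
};

static const char *SCALAR_NAMES[NSCALAR] = {
  "DC.resting.lymphoid", "DC.active.lymphoid",
  "Macrophage.resting.lymphoid", "Macrophage.active.lymphoid",
  "Th1.active.lymphoid", "Th2.active.lymphoid", "Th17.active.lymphoid",
  "Treg.active.lymphoid", "CD8.active.lymphoid",
  "B_active.active.lymphoid", "B_memory.memory.lymphoid",
  "B_plasma.active.lymphoid", "IgG.level.lymphoid",
  "CD4.resting.blood", "CD8.resting.blood", "B_naive.resting.blood",
  "Neutrophil.resting.blood",
  "Th1.active.CNS", "Th17.active.CNS", "CD8.active.CNS",
  "Macrophage.active.CNS", "Neutrophil.active.CNS",
  "Th_naive.resting.CNS", "B_naive.resting.CNS", "B_active.active.CNS",
  "B_plasma.active.CNS", "IgG.level.CNS",
  "Microglia.resting.CNS", "Microglia.active.CNS",
  "Astrocyte.resting.CNS", "Astrocyte.active.CNS",
  "ODC.resting.CNS", "bbb_permeability", "MBP.level.lymphoid", "drug_level"
};

static const char *CYT_NAMES[NCYT] = {
  "IL-1", "IL-2", "IL-4", "IL-5", "IL-6", "IL-10", "IL-12", "IL-13",
  "IL-17", "IL-21", "IL-22", "IL-23", "TNF-a", "TNF-b", "IFN-g", "TGF-b"
};
static const char *COMP_NAMES[NCOMP] = { "lymphoid", "blood", "CNS" };

struct Par {
  int K;                       // clones per adaptive lineage
  // set-points
  double sp_dc, sp_mac, sp_micro, sp_astro, sp_treg;
  double sp_thn, sp_cd8n, sp_bn;
  double sp_cd4b, sp_cd8b, sp_bb, sp_neutb;
  // homeostasis / turnover
  double p_home_naive, p_home_innate, p_home_treg;
  double rec_cd4, rec_cd8, rec_b, rec_neut;
  // death rates
  double d_th, d_cd8a, d_bact, d_bmem, d_bpla, d_macact, d_dcact;
  double d_cns, d_neutcns, d_ncns, d_bactcns, d_bplacns, d_igg;
  double d_microact, d_astroact;
  // cytokines
  double cyt_decay, q_sec, gate_K, il10_thr, tgfb_source;
  // disease layer
  int disease_on;
  double k_dc, K_mbp, k_act, k_act8, k_b, p_pla, p_mem, q_igg, p_prolif;
  double ebv_magnitude;
  double bbb_base, K_bbb, perm_damage_thr, m0_mig, p_naive_mig;
  double k_mic, k_ast, k_neut, k_sec, p_treg_exp, il10_act_damp, mbp_uptake;
  double r_igg, r_cd8, r_mac, r_neut, r_regen;
  double mbp_per_kill, mbp_decay, mbp_base;
  double odc_cap;
  // treatment layer
  int drug;                    // 0 none/placebo, 1 cladribine, 2 ocrelizumab, 3 ifnb1a
  double hl_drug, k_clad_cd4, k_clad_cd8, k_clad_b, k_ocr, ocr_thr, ocr_tmod;
  double ifn_act_red, ifn_bbb_red, sens;
  // patient
  double hla;
};

static double getp(const NumericVector &p, const char *nm) {
  if (!p.containsElementNamed(nm))
    stop(std::string("engine parameter missing: ") + nm);
  return as<double>(p[nm]);
}

static Par parsePar(const NumericVector &p) {
  Par q;
  q.K = (int)getp(p, "n_clones");
  q.sp_dc = getp(p, "sp_dc"); q.sp_mac = getp(p, "sp_mac");
  q.sp_micro = getp(p, "sp_micro"); q.sp_astro = getp(p, "sp_astro");
  q.sp_treg = getp(p, "sp_treg");
  q.sp_thn = getp(p, "sp_thn"); q.sp_cd8n = getp(p, "sp_cd8n");
  q.sp_bn = getp(p, "sp_bn");
  q.sp_cd4b = getp(p, "sp_cd4_blood"); q.sp_cd8b = getp(p, "sp_cd8_blood");
  q.sp_bb = getp(p, "sp_b_blood"); q.sp_neutb = getp(p, "sp_neut_blood");
  q.p_home_naive = getp(p, "p_home_naive");
  q.p_home_innate = getp(p, "p_home_innate");
  q.p_home_treg = getp(p, "p_home_treg");
  q.rec_cd4 = getp(p, "rec_cd4"); q.rec_cd8 = getp(p, "rec_cd8");
  q.rec_b = getp(p, "rec_b"); q.rec_neut = getp(p, "rec_neut");
  q.d_th = getp(p, "d_th"); q.d_cd8a = getp(p, "d_cd8a");
  q.d_bact = getp(p, "d_bact"); q.d_bmem = getp(p, "d_bmem");
  q.d_bpla = getp(p, "d_bpla"); q.d_macact = getp(p, "d_macact");
  q.d_dcact = getp(p, "d_dcact");
  q.d_cns = getp(p, "d_cns"); q.d_neutcns = getp(p, "d_neutcns");
  q.d_ncns = getp(p, "d_ncns"); q.d_bactcns = getp(p, "d_bactcns");
  q.d_bplacns = getp(p, "d_bplacns"); q.d_igg = getp(p, "d_igg");
  q.d_microact = getp(p, "d_microact"); q.d_astroact = getp(p, "d_astroact");
  q.cyt_decay = getp(p, "cyt_decay"); q.q_sec = getp(p, "q_sec");
  q.gate_K = getp(p, "gate_K"); q.il10_thr = getp(p, "il10_thr");
  q.tgfb_source = getp(p, "tgfb_source");
  q.disease_on = (int)getp(p, "disease_on");
  q.k_dc = getp(p, "k_dc"); q.K_mbp = getp(p, "K_mbp");
  q.k_act = getp(p, "k_act"); q.k_act8 = getp(p, "k_act8");
  q.k_b = getp(p, "k_b"); q.p_pla = getp(p, "p_pla"); q.p_mem = getp(p, "p_mem");
  q.q_igg = getp(p, "q_igg"); q.p_prolif = getp(p, "p_prolif");
  q.ebv_magnitude = getp(p, "ebv_magnitude");
  q.bbb_base = getp(p, "bbb_base"); q.K_bbb = getp(p, "K_bbb");
  q.perm_damage_thr = getp(p, "perm_damage_thr");
  q.m0_mig = getp(p, "m0_mig"); q.p_naive_mig = getp(p, "p_naive_mig");
  q.k_mic = getp(p, "k_mic"); q.k_ast = getp(p, "k_ast");
  q.k_neut = getp(p, "k_neut"); q.k_sec = getp(p, "k_sec");
  q.p_treg_exp = getp(p, "p_treg_exp");
  q.il10_act_damp = getp(p, "il10_act_damp");
  q.mbp_uptake = getp(p, "mbp_uptake");
  q.r_igg = getp(p, "r_igg"); q.r_cd8 = getp(p, "r_cd8");
  q.r_mac = getp(p, "r_mac"); q.r_neut = getp(p, "r_neut");
  q.r_regen = getp(p, "r_regen");
  q.mbp_per_kill = getp(p, "mbp_per_kill"); q.mbp_decay = getp(p, "mbp_decay");
  q.mbp_base = getp(p, "mbp_base");
  q.odc_cap = getp(p, "odc_cap");
  q.drug = (int)getp(p, "drug");
  q.hl_drug = getp(p, "hl_drug");
  q.k_clad_cd4 = getp(p, "k_clad_cd4"); q.k_clad_cd8 = getp(p, "k_clad_cd8");
  q.k_clad_b = getp(p, "k_clad_b"); q.k_ocr = getp(p, "k_ocr");
  q.ocr_thr = getp(p, "ocr_thr"); q.ocr_tmod = getp(p, "ocr_tmod");
  q.ifn_act_red = getp(p, "ifn_act_red"); q.ifn_bbb_red = getp(p, "ifn_bbb_red");
  q.sens = getp(p, "sens");
  q.hla = getp(p, "hla");
  return q;
}

static inline int cytIdx(int comp, int c) { return NSCALAR + comp * NCYT + c; }
static inline int clIdx(int K, int lineage, int i) {
  return NSCALAR + NCOMP * NCYT + lineage * K + i;
}
static inline double rbin(double n, double p) {
  if (n < 1.0 || p <= 0.0) return 0.0;
  if (p >= 1.0) return std::floor(n);
  return R::rbinom(std::floor(n), p);
}
static inline double gate(double level, double K) {
  if (level <= 0.0) return 0.0;
  return level / (level + K);
}

// ---------------------------------------------------------------- physiology

static void hematopoiesis(double *s, const Par &p) {
  // naive clonal pools: binomial birth toward set-point, matched death
  double sp_cl[3] = { p.sp_thn / p.K, p.sp_cd8n / p.K, p.sp_bn / p.K };
  for (int l = 0; l < 3; ++l)
    for (int i = 0; i < p.K; ++i) {
      int ix = clIdx(p.K, l, i);
      s[ix] += rbin(sp_cl[l], p.p_home_naive) - rbin(s[ix], p.p_home_naive);
    }
  // circulating pools (slow turnover; recovery rate differs per lineage)
  s[CD4_BLOOD] += rbin(p.sp_cd4b, p.rec_cd4) - rbin(s[CD4_BLOOD], p.rec_cd4);
  s[CD8_BLOOD] += rbin(p.sp_cd8b, p.rec_cd8) - rbin(s[CD8_BLOOD], p.rec_cd8);
  s[B_BLOOD]   += rbin(p.sp_bb,   p.rec_b)   - rbin(s[B_BLOOD],   p.rec_b);
  s[NEUT_BLOOD]+= rbin(p.sp_neutb,p.rec_neut)- rbin(s[NEUT_BLOOD],p.rec_neut);
  // resting innate pools
  s[DC_REST]   += rbin(p.sp_dc,   p.p_home_innate) - rbin(s[DC_REST],   p.p_home_innate);
  s[MAC_REST]  += rbin(p.sp_mac,  p.p_home_innate) - rbin(s[MAC_REST],  p.p_home_innate);
  s[MICRO_REST]+= rbin(p.sp_micro,p.p_home_innate) - rbin(s[MICRO_REST],p.p_home_innate);
  s[ASTRO_REST]+= rbin(p.sp_astro,p.p_home_innate) - rbin(s[ASTRO_REST],p.p_home_innate);
  s[TREG_LYM]  += rbin(p.sp_treg, p.p_home_treg)   - rbin(s[TREG_LYM],  p.p_home_treg);
}

static void deaths(double *s, const Par &p) {
  s[DC_ACT]   -= rbin(s[DC_ACT],   p.d_dcact);
  s[MAC_ACT]  -= rbin(s[MAC_ACT],  p.d_macact);
  s[TH1_LYM]  -= rbin(s[TH1_LYM],  p.d_th);
  s[TH2_LYM]  -= rbin(s[TH2_LYM],  p.d_th);
  s[TH17_LYM] -= rbin(s[TH17_LYM], p.d_th);
  s[CD8A_LYM] -= rbin(s[CD8A_LYM], p.d_cd8a);
  s[BACT_LYM] -= rbin(s[BACT_LYM], p.d_bact);
  s[BMEM_LYM] -= rbin(s[BMEM_LYM], p.d_bmem);
  s[BPLA_LYM] -= rbin(s[BPLA_LYM], p.d_bpla);
  s[TH1_CNS]  -= rbin(s[TH1_CNS],  p.d_cns);
  s[TH17_CNS] -= rbin(s[TH17_CNS], p.d_cns);
  s[CD8A_CNS] -= rbin(s[CD8A_CNS], p.d_cns);
  s[MAC_CNS]  -= rbin(s[MAC_CNS],  p.d_cns);
  s[NEUT_CNS] -= rbin(s[NEUT_CNS], p.d_neutcns);
  s[TN_CNS]   -= rbin(s[TN_CNS],   p.d_ncns);
  s[BN_CNS]   -= rbin(s[BN_CNS],   p.d_ncns);
  s[BACT_CNS] -= rbin(s[BACT_CNS], p.d_bactcns);
  s[BPLA_CNS] -= rbin(s[BPLA_CNS], p.d_bplacns);
  s[MICRO_ACT]-= rbin(s[MICRO_ACT],p.d_microact);
  s[ASTRO_ACT]-= rbin(s[ASTRO_ACT],p.d_astroact);
  s[IGG_LYM]  *= (1.0 - p.d_igg);
  s[IGG_CNS]  *= (1.0 - p.d_igg);
}

static void secreteAndDecay(double *s, const Par &p) {
  double q = p.q_sec;
  double add[NCOMP][NCYT];
  for (int c = 0; c < NCOMP; ++c)
    for (int k = 0; k < NCYT; ++k) add[c][k] = 0.0;
  // lymphoid secretors
  add[LYM][IL12] += q * (s[DC_ACT] + s[MAC_ACT]);
  add[LYM][IL6]  += q * (s[DC_ACT] + s[MAC_ACT]);
  add[LYM][IL23] += q * s[DC_ACT];
  add[LYM][IL1]  += q * (s[DC_ACT] + s[MAC_ACT]);
  add[LYM][TNFA] += q * (s[MAC_ACT] + s[TH1_LYM] + s[TH17_LYM]);
  add[LYM][IFNG] += q * s[TH1_LYM];
  add[LYM][IL2]  += q * s[TH1_LYM];
  add[LYM][IL4]  += q * s[TH2_LYM];
  add[LYM][IL5]  += q * s[TH2_LYM];
  add[LYM][IL13] += q * s[TH2_LYM];
  add[LYM][IL10] += q * s[TH2_LYM];
  add[LYM][IL17] += q * s[TH17_LYM];
  add[LYM][IL6]  += q * s[TH17_LYM];
  add[LYM][IL21] += q * s[TH17_LYM];
  add[LYM][IL22] += q * s[TH17_LYM];
  add[LYM][IL23] += q * s[TH17_LYM];
  // Tregs damp inflammation: IL-10 release scales with the ongoing
  // inflammatory signal (IL-2 from Th1, IL-12 from active APCs)
  double il2g = gate(s[cytIdx(LYM, IL2)] + s[cytIdx(LYM, IL12)], p.gate_K);
  // expanded Tregs also secrete constitutively, so the anti-inflammatory
  // veto outlasts the attack and relaxes on the Treg-contraction timescale
  double treg_x = s[TREG_LYM] - p.sp_treg; if (treg_x < 0) treg_x = 0;
  add[LYM][IL10] += 3.0 * q * (s[TREG_LYM] * il2g + treg_x);
  add[LYM][TGFB] += q * s[TREG_LYM] * il2g + p.tgfb_source;
  // CNS secretors
  add[CNS][IL1]  += q * (s[MICRO_ACT] + s[ASTRO_ACT]);
  add[CNS][IL6]  += q * (s[MICRO_ACT] + s[ASTRO_ACT] + s[TH17_CNS]);
  add[CNS][IL12] += q * s[MICRO_ACT];
  add[CNS][TNFA] += q * (s[MICRO_ACT] + s[ASTRO_ACT] + s[TH1_CNS] + s[TH17_CNS]);
  add[CNS][IFNG] += q * (s[MICRO_ACT] + s[TH1_CNS]);
  add[CNS][IL2]  += q * (s[MICRO_ACT] + s[TH1_CNS]);
  add[CNS][IL17] += q * s[TH17_CNS];
  add[CNS][IL22] += q * s[TH17_CNS];
  add[CNS][IL23] += q * s[TH17_CNS];
  // IL-10 above threshold inhibits synthesis of the Th-related
  // pro-inflammatory mediators (IFN-g, TNF-a/b, IL-1, IL-2, IL-6)
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) {
    const int damped[6] = { IFNG, TNFA, TNFB, IL1, IL2, IL6 };
    for (int j = 0; j < 6; ++j) add[LYM][damped[j]] *= p.il10_act_damp;
  }
  for (int c = 0; c < NCOMP; ++c)
    for (int k = 0; k < NCYT; ++k) {
      int ix = cytIdx(c, k);
      s[ix] = (s[ix] + add[c][k]) * p.cyt_decay;
      if (s[ix] < 0) s[ix] = 0;
    }
}

// ------------------------------------------------------------- disease layer

// partition newly activated CD4 cells into helper subsets under the milieu
static void differentiate(double n_act, const double *s, const Par &p,
                          double out[4]) {
  out[0] = out[1] = out[2] = out[3] = 0.0;
  if (n_act < 1.0) return;
  double K = p.gate_K;
  double w1 = 0.15 + gate(s[cytIdx(LYM, IL12)], K) * gate(s[cytIdx(LYM, IFNG)], K);
  double w17 = 0.15 + gate(s[cytIdx(LYM, IL6)], K) *
               0.5 * (gate(s[cytIdx(LYM, IL23)], K) + gate(s[cytIdx(LYM, TGFB)], K));
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) w17 = 0.0;  // hard IL-10 veto
  double w2 = 0.15 + gate(s[cytIdx(LYM, IL4)], K);
  double supp = 1.0 / (1.0 + s[TREG_LYM] / 200.0);    // Treg suppression
  double wsum = w1 + w17 + w2;
  double n = std::floor(n_act);
  // sequential multinomial thinning over {Th1, Th17, Th2, suppressed}
  double p1 = supp * w1 / wsum;
  double p17 = supp * w17 / wsum;
  double p2 = supp * w2 / wsum;
  double n1 = rbin(n, p1);
  double n17 = (1.0 - p1 > 1e-12) ? rbin(n - n1, p17 / (1.0 - p1)) : 0.0;
  double n2 = (1.0 - p1 - p17 > 1e-12)
                ? rbin(n - n1 - n17, p2 / (1.0 - p1 - p17)) : 0.0;
  out[0] = n1; out[1] = n17; out[2] = n2;
  out[3] = n - n1 - n17 - n2;  // Treg-suppressed remainder (stays naive)
}

static void presentAntigen(double *s, const Par &p, const NumericVector &w4,
                           const NumericVector &w8, double act_scale) {
  // IL-10 above threshold suppresses antigen-specific priming
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) act_scale *= p.il10_act_damp;
  // inflammation-driven Treg expansion (delayed negative feedback)
  double ginf = gate(s[cytIdx(LYM, IL12)], p.gate_K);
  s[TREG_LYM] += rbin(s[TREG_LYM], p.p_treg_exp * ginf);
  double mbp = s[MBP] + p.mbp_base;
  // sharp (Hill-2) antigen threshold: trace debris does not sustain
  // presentation, so the system fully rests between attacks
  double p_dc = p.k_dc * (mbp * mbp) / (mbp * mbp + p.K_mbp * p.K_mbp);
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) p_dc *= p.il10_act_damp;
  double newdc = rbin(s[DC_REST], p_dc);
  s[DC_REST] -= newdc; s[DC_ACT] += newdc;
  // antigen digestion: processing DCs consume MBP, so residual debris
  // clears once destruction stops
  s[MBP] *= 1.0 - std::min(0.5, p.mbp_uptake * s[DC_ACT]);
  if (s[DC_ACT] < 1.0) return;
  double drive = s[DC_ACT] / (s[DC_ACT] + 100.0);
  double tot4 = 0.0;
  for (int i = 0; i < p.K; ++i) {
    if (w4[i] <= 0) continue;
    int ix = clIdx(p.K, 0, i);
    double pr = 1.0 - std::exp(-p.k_act * act_scale * p.hla * w4[i] * drive);
    double a = rbin(s[ix], pr);
    s[ix] -= a; tot4 += a;
  }
  if (tot4 > 0) {
    double out[4];
    differentiate(tot4, s, p, out);
    s[TH1_LYM] += out[0]; s[TH17_LYM] += out[1]; s[TH2_LYM] += out[2];
    // suppressed remainder returns to the naive pool (spread over reactive clones)
    if (out[3] > 0) {
      for (int i = 0; i < p.K && out[3] > 0; ++i)
        if (w4[i] > 0) { s[clIdx(p.K, 0, i)] += out[3]; break; }
    }
  }
  for (int i = 0; i < p.K; ++i) {
    if (w8[i] <= 0) continue;
    int ix = clIdx(p.K, 1, i);
    double pr = 1.0 - std::exp(-p.k_act8 * act_scale * p.hla * w8[i] * drive);
    double a = rbin(s[ix], pr);
    s[ix] -= a; s[CD8A_LYM] += a;
  }
  // mild antigen-driven proliferation of activated pools under IL-2,
  // Treg-suppressed so expansion stays subcritical
  double supp = 1.0 / (1.0 + s[TREG_LYM] / 200.0);
  double pg = p.p_prolif * supp * gate(s[cytIdx(LYM, IL2)], p.gate_K);
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) pg *= p.il10_act_damp;
  s[TH1_LYM] += rbin(s[TH1_LYM], pg);
  s[TH17_LYM] += rbin(s[TH17_LYM], pg);
  s[CD8A_LYM] += rbin(s[CD8A_LYM], pg);
  // Th1-driven macrophage activation (IFN-g / TNF-a)
  double pm = 0.1 * gate(s[cytIdx(LYM, IFNG)], p.gate_K) *
              gate(s[cytIdx(LYM, TNFA)], p.gate_K);
  double m = rbin(s[MAC_REST], pm);
  s[MAC_REST] -= m; s[MAC_ACT] += m;
}

static void activateBCells(double *s, const Par &p, const NumericVector &wb,
                           double act_scale) {
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) act_scale *= p.il10_act_damp;
  double K = p.gate_K;
  double g = 0.2 * (gate(s[cytIdx(LYM, IL4)], K) + gate(s[cytIdx(LYM, IL5)], K) +
                    gate(s[cytIdx(LYM, IL6)], K) + gate(s[cytIdx(LYM, IL10)], K) +
                    gate(s[cytIdx(LYM, IL13)], K));
  double th2 = s[TH2_LYM] / (s[TH2_LYM] + 50.0);
  for (int i = 0; i < p.K; ++i) {
    if (wb[i] <= 0) continue;
    int ix = clIdx(p.K, 2, i);
    double pr = 1.0 - std::exp(-p.k_b * act_scale * wb[i] * th2 * g);
    double a = rbin(s[ix], pr);
    s[ix] -= a; s[BACT_LYM] += a;
  }
  // duplication and differentiation to plasma / memory (Treg-suppressed)
  double suppb = 1.0 / (1.0 + s[TREG_LYM] / 200.0);
  s[BACT_LYM] += rbin(s[BACT_LYM],
                      p.p_prolif * suppb * gate(s[cytIdx(LYM, IL4)], K));
  double pl = rbin(s[BACT_LYM], p.p_pla);
  double me = rbin(s[BACT_LYM] - pl, p.p_mem);
  s[BACT_LYM] -= (pl + me); s[BPLA_LYM] += pl; s[BMEM_LYM] += me;
  s[IGG_LYM] += p.q_igg * s[BPLA_LYM];
  // CNS plasma cells secrete locally
  s[IGG_CNS] += p.q_igg * s[BPLA_CNS];
}

static void ebvMimicry(double *s, const Par &p, const NumericVector &w4,
                       const NumericVector &w8, const NumericVector &wb,
                       double magnitude) {
  if (magnitude <= 0) return;
  double tot4 = 0;
  for (int i = 0; i < p.K; ++i) {
    if (w4[i] > 0) {
      int ix = clIdx(p.K, 0, i);
      double a = rbin(s[ix], magnitude * w4[i]);
      s[ix] -= a; tot4 += a;
    }
    if (w8[i] > 0) {
      int ix = clIdx(p.K, 1, i);
      double a = rbin(s[ix], magnitude * w8[i]);
      s[ix] -= a; s[CD8A_LYM] += a;
    }
    if (wb[i] > 0) {
      int ix = clIdx(p.K, 2, i);
      double a = rbin(s[ix], magnitude * wb[i]);
      s[ix] -= a; s[BACT_LYM] += a;
    }
  }
  if (tot4 > 0) {
    double out[4];
    differentiate(tot4, s, p, out);
    s[TH1_LYM] += out[0]; s[TH17_LYM] += out[1]; s[TH2_LYM] += out[2];
    // suppressed remainder becomes anergic (leaves the active pools)
  }
}

static double damageBbb(const double *s, const Par &p, double bbb_red) {
  double K = p.gate_K;
  double W = s[cytIdx(LYM, IFNG)] + s[cytIdx(LYM, TNFA)] + s[cytIdx(LYM, TNFB)] +
             s[cytIdx(LYM, IL17)] + s[cytIdx(LYM, IL6)] + s[cytIdx(LYM, IL1)] +
             0.5 * s[cytIdx(LYM, IL22)];
  W *= (1.0 - bbb_red);
  return p.bbb_base + (1.0 - p.bbb_base) * W / (W + p.K_bbb);
}

static void migrateToCns(double *s, const Par &p) {
  double K = p.gate_K, perm = s[BBB];
  bool il10_block = s[cytIdx(LYM, IL10)] >= p.il10_thr;
  double g1 = gate(s[cytIdx(LYM, IL12)], K);
  double g17 = 0.25 * (gate(s[cytIdx(LYM, IL17)], K) + gate(s[cytIdx(LYM, IL6)], K) +
                       gate(s[cytIdx(LYM, IL22)], K) + gate(s[cytIdx(LYM, IL23)], K));
  double gm = gate(s[cytIdx(LYM, TNFA)], K);
  if (!il10_block) {
    double m;
    m = rbin(s[TH1_LYM], p.m0_mig * perm * g1);  s[TH1_LYM] -= m; s[TH1_CNS] += m;
    m = rbin(s[TH17_LYM], p.m0_mig * perm * g17); s[TH17_LYM] -= m; s[TH17_CNS] += m;
    m = rbin(s[MAC_ACT], p.m0_mig * perm * gm);  s[MAC_ACT] -= m; s[MAC_CNS] += m;
    double ig = s[IGG_LYM] * p.m0_mig * perm;    s[IGG_LYM] -= ig; s[IGG_CNS] += ig;
  }
  // CD8 egress is not under the IL-10 veto
  double m8 = rbin(s[CD8A_LYM], p.m0_mig * perm * 0.6);
  s[CD8A_LYM] -= m8; s[CD8A_CNS] += m8;
  // resting cells cross only a damaged barrier
  if (perm > p.perm_damage_thr) {
    for (int i = 0; i < p.K; ++i) {
      int ix = clIdx(p.K, 0, i);
      double m = rbin(s[ix], p.p_naive_mig * perm);
      s[ix] -= m; s[TN_CNS] += m;
      ix = clIdx(p.K, 2, i);
      m = rbin(s[ix], p.p_naive_mig * perm);
      s[ix] -= m; s[BN_CNS] += m;
    }
  }
}

static void cnsReactivation(double *s, const Par &p) {
  double K = p.gate_K;
  double th = s[TH1_CNS] + s[TH17_CNS];
  if (th >= 1.0) {
    double pm = p.k_mic * th / (th + 100.0);
    double m = rbin(s[MICRO_REST], pm);
    s[MICRO_REST] -= m; s[MICRO_ACT] += m;
  }
  double pa = p.k_ast * 0.5 * (gate(s[cytIdx(CNS, IL1)], K) + gate(s[cytIdx(CNS, TNFA)], K));
  double a = rbin(s[ASTRO_REST], pa);
  s[ASTRO_REST] -= a; s[ASTRO_ACT] += a;
  // IL-17 recruits neutrophils from blood across the damaged barrier
  double pn = p.k_neut * gate(s[cytIdx(CNS, IL17)], K) * s[BBB];
  double n = rbin(s[NEUT_BLOOD], pn);
  s[NEUT_BLOOD] -= n; s[NEUT_CNS] += n;
  // secondary activation of naive cells that crossed a damaged barrier
  double ps = p.k_sec * gate(s[cytIdx(CNS, IL12)], K);
  if (s[cytIdx(LYM, IL10)] >= p.il10_thr) ps *= p.il10_act_damp;
  double t = rbin(s[TN_CNS], ps);
  s[TN_CNS] -= t; s[TH1_CNS] += rbin(t, 0.7); s[TH17_CNS] += t - rbin(t, 0.7);
  // note: split drawn once; acceptable approximation of a binomial split
  double b = rbin(s[BN_CNS], ps);
  s[BN_CNS] -= b; s[BACT_CNS] += b;
  double pl = rbin(s[BACT_CNS], p.p_pla);
  s[BACT_CNS] -= pl; s[BPLA_CNS] += pl;
}

// returns ODC loss this tick
static double killOligodendrocytes(double *s, const Par &p) {
  double K = p.gate_K;
  // effectors attack under the influence of the local inflammatory milieu;
  // a quiescent CNS supports almost no killing, which lets the tissue rest
  double cg = 0.05 + gate(s[cytIdx(CNS, TNFA)], K) + gate(s[cytIdx(CNS, IFNG)], K);
  if (cg > 1.0) cg = 1.0;
  double f1 = std::min(0.999, p.r_cd8 * s[CD8A_CNS] * cg);
  double f2 = std::min(0.999, p.r_mac * s[MAC_CNS] * cg);
  double f3 = std::min(0.999, p.r_igg * s[IGG_CNS] * cg);
  double f4 = std::min(0.999, p.r_neut * s[NEUT_CNS] * cg);
  double hazard = 1.0 - (1.0 - f1) * (1.0 - f2) * (1.0 - f3) * (1.0 - f4);
  double loss = rbin(s[ODC], hazard);
  s[ODC] -= loss;
  // slow regeneration toward capacity between attacks
  s[ODC] += rbin(p.odc_cap - s[ODC], p.r_regen);
  if (s[ODC] > p.odc_cap) s[ODC] = p.odc_cap;
  // myelin debris feeds antigen presentation
  s[MBP] = s[MBP] * p.mbp_decay + p.mbp_per_kill * loss;
  if (s[MBP] > 500.0) s[MBP] = 500.0;
  return loss;
}

// ------------------------------------------------------------ treatment layer

static void applyTreatment(double *s, const Par &p, bool dose_now, double amt,
                           double *act_scale, double *bbb_red) {
  *act_scale = 1.0; *bbb_red = 0.0;
  if (p.drug == 0) return;
  if (dose_now) s[DRUG_LEVEL] += amt;
  double lvl = s[DRUG_LEVEL];
  if (p.drug == 1) {            // cladribine: lymphotoxic to T and B lineages
    if (lvl > 1e-8) {
      double p4 = 1.0 - std::exp(-p.k_clad_cd4 * p.sens * lvl);
      double p8 = 1.0 - std::exp(-p.k_clad_cd8 * p.sens * lvl);
      double pb = 1.0 - std::exp(-p.k_clad_b * p.sens * lvl);
      s[CD4_BLOOD] -= rbin(s[CD4_BLOOD], p4);
      s[CD8_BLOOD] -= rbin(s[CD8_BLOOD], p8);
      s[B_BLOOD]   -= rbin(s[B_BLOOD], pb);
      for (int i = 0; i < p.K; ++i) {
        int i4 = clIdx(p.K, 0, i), i8 = clIdx(p.K, 1, i), ib = clIdx(p.K, 2, i);
        s[i4] -= rbin(s[i4], p4);
        s[i8] -= rbin(s[i8], p8);
        s[ib] -= rbin(s[ib], pb);
      }
      s[TH1_LYM] -= rbin(s[TH1_LYM], p4); s[TH2_LYM] -= rbin(s[TH2_LYM], p4);
      s[TH17_LYM] -= rbin(s[TH17_LYM], p4); s[TREG_LYM] -= rbin(s[TREG_LYM], p4);
      s[CD8A_LYM] -= rbin(s[CD8A_LYM], p8);
      s[BACT_LYM] -= rbin(s[BACT_LYM], pb); s[BMEM_LYM] -= rbin(s[BMEM_LYM], pb);
    }
  } else if (p.drug == 2) {     // ocrelizumab: anti-CD20, plasma cells spared
    if (lvl > p.ocr_thr) {
      double pb = 1.0 - std::exp(-p.k_ocr * p.sens * std::min(lvl, 1.5));
      s[B_BLOOD] -= rbin(s[B_BLOOD], pb);
      for (int i = 0; i < p.K; ++i) {
        int ib = clIdx(p.K, 2, i);
        s[ib] -= rbin(s[ib], pb);
      }
      s[BACT_LYM] -= rbin(s[BACT_LYM], pb);
      s[BMEM_LYM] -= rbin(s[BMEM_LYM], pb);
      s[BACT_CNS] -= rbin(s[BACT_CNS], pb);
      s[BN_CNS]   -= rbin(s[BN_CNS], pb);
      *act_scale = 1.0 - p.ocr_tmod * std::min(lvl, 1.0);  // mild T modulation
    }
  } else if (p.drug == 3) {     // IFN beta-1a: damps Th activation and BBB damage
    double e = std::min(lvl, 1.0);
    *act_scale = 1.0 - p.ifn_act_red * e;
    *bbb_red = p.ifn_bbb_red * e;
  }
  s[DRUG_LEVEL] *= std::exp(-M_LN2 / p.hl_drug);
}

// ------------------------------------------------------------------ full tick

static double tickOnce(double *s, const Par &p,
                       const NumericVector &w4, const NumericVector &w8,
                       const NumericVector &wb, bool ebv_now, bool dose_now,
                       double dose_amt) {
  double act_scale = 1.0, bbb_red = 0.0;
  // treatment effect parameters for this tick are read before disease rules so
  // activation-rate modulation (ocrelizumab, IFN) acts on the same tick
  // physiology
  hematopoiesis(s, p);
  deaths(s, p);
  secreteAndDecay(s, p);
  double loss = 0.0;
  // treatment (depletion acts after physiology, before disease readout)
  applyTreatment(s, p, dose_now, dose_amt, &act_scale, &bbb_red);
  if (p.disease_on) {
    presentAntigen(s, p, w4, w8, act_scale);
    activateBCells(s, p, wb, act_scale);
    if (ebv_now) ebvMimicry(s, p, w4, w8, wb, p.ebv_magnitude);
    s[BBB] = damageBbb(s, p, bbb_red);
    migrateToCns(s, p);
    cnsReactivation(s, p);
    loss = killOligodendrocytes(s, p);
  }
  // clamp
  int n = NSCALAR + NCOMP * NCYT + 3 * p.K;
  for (int i = 0; i < n; ++i) if (s[i] < 0) s[i] = 0;
  if (s[BBB] > 1) s[BBB] = 1;
  return loss;
}

// ------------------------------------------------------------------- exports

// [[Rcpp::export]]
CharacterVector cpp_state_names(int n_clones) {
  CharacterVector out(NSCALAR + NCOMP * NCYT + 3 * n_clones);
  for (int i = 0; i < NSCALAR; ++i) out[i] = SCALAR_NAMES[i];
  for (int c = 0; c < NCOMP; ++c)
    for (int k = 0; k < NCYT; ++k)
      out[cytIdx(c, k)] = std::string("cyt.") + CYT_NAMES[k] + "." + COMP_NAMES[c];
  const char *lin[3] = { "Th_naive", "CD8_naive", "B_naive" };
  for (int l = 0; l < 3; ++l)
    for (int i = 0; i < n_clones; ++i)
      out[clIdx(n_clones, l, i)] =
        std::string(lin[l]) + ".clone" + std::to_string(i + 1) + ".lymphoid";
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tick(NumericVector state, NumericVector par,
                       NumericVector w4, NumericVector w8, NumericVector wb,
                       bool ebv_now, bool dose_now, double dose_amt) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  tickOnce(s.begin(), p, w4, w8, wb, ebv_now, dose_now, dose_amt);
  return s;
}

// Runs n_ticks and records tick-wise series needed by the outcome layer.
// ebv_ticks / dose_ticks are 1-based tick indices.
// [[Rcpp::export]]
List cpp_run(NumericVector state, NumericVector par,
             NumericVector w4, NumericVector w8, NumericVector wb,
             IntegerVector ebv_ticks, IntegerVector dose_ticks,
             NumericVector dose_amts, int n_ticks, int snapshot_every = 0) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  NumericVector odc(n_ticks), alc_raw(n_ticks), loss(n_ticks);
  NumericVector cd4(n_ticks), cd8(n_ticks), bb(n_ticks);
  std::vector<bool> is_ebv(n_ticks + 1, false), is_dose(n_ticks + 1, false);
  std::vector<double> amt(n_ticks + 1, 0.0);
  for (int i = 0; i < ebv_ticks.size(); ++i)
    if (ebv_ticks[i] >= 1 && ebv_ticks[i] <= n_ticks) is_ebv[ebv_ticks[i]] = true;
  for (int i = 0; i < dose_ticks.size(); ++i)
    if (dose_ticks[i] >= 1 && dose_ticks[i] <= n_ticks) {
      is_dose[dose_ticks[i]] = true;
      amt[dose_ticks[i]] += dose_amts[i];
    }
  int n_snap = (snapshot_every > 0) ? n_ticks / snapshot_every : 0;
  NumericMatrix snaps(n_snap, s.size());
  int si = 0;
  for (int t = 1; t <= n_ticks; ++t) {
    loss[t - 1] = tickOnce(s.begin(), p, w4, w8, wb, is_ebv[t], is_dose[t], amt[t]);
    odc[t - 1] = s[ODC];
    cd4[t - 1] = s[CD4_BLOOD]; cd8[t - 1] = s[CD8_BLOOD]; bb[t - 1] = s[B_BLOOD];
    alc_raw[t - 1] = s[CD4_BLOOD] + s[CD8_BLOOD] + s[B_BLOOD];
    if (snapshot_every > 0 && t % snapshot_every == 0 && si < n_snap)
      snaps(si++, _) = s;
  }
  return List::create(_["state"] = s, _["odc"] = odc, _["loss"] = loss,
                      _["alc_raw"] = alc_raw, _["cd4_blood"] = cd4,
                      _["cd8_blood"] = cd8, _["b_blood"] = bb,
                      _["snapshots"] = snaps);
}

// --- thin exports of individual rules (same subroutines the tick composes) ---

// [[Rcpp::export]]
NumericVector cpp_hematopoiesis(NumericVector state, NumericVector par) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  hematopoiesis(s.begin(), p);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_secrete_decay(NumericVector state, NumericVector par) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  secreteAndDecay(s.begin(), p);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_present_antigen(NumericVector state, NumericVector par,
                                  NumericVector w4, NumericVector w8,
                                  double act_scale = 1.0) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  presentAntigen(s.begin(), p, w4, w8, act_scale);
  for (int i = 0; i < s.size(); ++i) if (s[i] < 0) s[i] = 0;
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_differentiate(double n_act, NumericVector state,
                                NumericVector par) {
  Par p = parsePar(par);
  double out[4];
  differentiate(n_act, REAL(state), p, out);
  return NumericVector::create(_["Th1"] = out[0], _["Th17"] = out[1],
                               _["Th2"] = out[2], _["suppressed"] = out[3]);
}

// [[Rcpp::export]]
NumericVector cpp_activate_b(NumericVector state, NumericVector par,
                             NumericVector wb, double act_scale = 1.0) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  activateBCells(s.begin(), p, wb, act_scale);
  for (int i = 0; i < s.size(); ++i) if (s[i] < 0) s[i] = 0;
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_ebv(NumericVector state, NumericVector par, NumericVector w4,
                      NumericVector w8, NumericVector wb, double magnitude) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  ebvMimicry(s.begin(), p, w4, w8, wb, magnitude);
  return s;
}

// [[Rcpp::export]]
double cpp_damage_bbb(NumericVector state, NumericVector par,
                      double bbb_red = 0.0) {
  Par p = parsePar(par);
  return damageBbb(REAL(state), p, bbb_red);
}

// [[Rcpp::export]]
NumericVector cpp_migrate(NumericVector state, NumericVector par) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  migrateToCns(s.begin(), p);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_cns_react(NumericVector state, NumericVector par) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  cnsReactivation(s.begin(), p);
  return s;
}

// [[Rcpp::export]]
List cpp_kill_odc(NumericVector state, NumericVector par) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  double loss = killOligodendrocytes(s.begin(), p);
  return List::create(_["state"] = s, _["loss"] = loss);
}

// [[Rcpp::export]]
List cpp_apply_treatment(NumericVector state, NumericVector par, bool dose_now,
                         double dose_amt) {
  Par p = parsePar(par);
  NumericVector s = clone(state);
  double act_scale, bbb_red;
  applyTreatment(s.begin(), p, dose_now, dose_amt, &act_scale, &bbb_red);
  for (int i = 0; i < s.size(); ++i) if (s[i] < 0) s[i] = 0;
  return List::create(_["state"] = s, _["act_scale"] = act_scale,
                      _["bbb_red"] = bbb_red);
}
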