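// Five-taxon MG94xHKY codon likelihood engine.
//
// The quintet topology is fixed: ((ppat,dpat)n1,(pmat,dmat)n2,out)n3 as an
// unrooted tree rooted (for computation) at n3.  Tip state vectors are
// one-hot, so partial likelihoods at the two cherries depend only on the
// observed (tip, tip) codon pair; the engine therefore evaluates cherries
// on the set of *unique* observed pairs and recombines per site pattern.
//
// The unnormalized symmetrized generator decomposes as
//   S_u = S_A + kappa S_B + omega (S_C + kappa S_D)
// (A = synonymous transversions, B = synonymous transitions,
//  C = nonsynonymous transversions, D = nonsynonymous transitions), with
// mean rate r = r_A + kappa r_B + omega (r_C + kappa r_D); the four
// component matrices are precomputed once, which makes both the
// per-branch eigendecompositions and the analytic gradient cheap.
//
// Branch order: 0 ppat, 1 dpat, 2 pmat, 3 dmat, 4 out, 5 n1-n3, 6 n2-n3.
// Parameter vector (log scale, length 15): log t[0..6], log omega[0..6],
// log kappa.  State 61 encodes a missing codon (gap/N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::as;

static const int NS = 61;       // sense codons
static const int MISS = 61;     // missing-data state

struct Engine {
  // data
  imat pat;                 // 5 x npat codon states (0..60, 61 missing)
  vec w;                    // pattern weights
  int npat;
  // model structure
  vec pi, sqp, isqp;        // stationary freqs and sqrt transforms
  mat SA, SB, SC, SD;       // symmetrized generator components
  double rA, rB, rC, rD;    // their stationary flow rates
  // cherry reduction
  uvec c1, c2, xo;          // per-pattern pair ids and outgroup state
  imat pairs1, pairs2;      // 2 x np: tip states of each unique pair
  int np1, np2;
  // committed caches (valid for lastpar)
  vec lastpar;
  mat V[7]; vec lam[7]; double rate[7];
  mat P[7];
  mat T1, T2, A1, A2;
  vec fp;
  double lnL;
  bool committed = false;
};

// ---- helpers ---------------------------------------------------------------

static void eig_branch(const Engine& e, double kappa, double omega,
                       mat& V, vec& lam, double& r) {
  r = e.rA + kappa * e.rB + omega * (e.rC + kappa * e.rD);
  if (r <= 0) r = 1e-12;
  mat S = (e.SA + kappa * e.SB + omega * (e.SC + kappa * e.SD)) / r;
  eig_sym(lam, V, S, "dc");
}

static void pmat_from_eig(const Engine& e, const mat& V, const vec& lam,
                          double t, mat& P) {
  vec el = exp(lam * t);
  mat M = V.each_row() % el.t();  // V * diag(el)
  mat E = M * V.t();
  P.set_size(NS, NS);
  for (int j = 0; j < NS; ++j)
    for (int i = 0; i < NS; ++i) {
      double v = e.isqp(i) * E(i, j) * e.sqp(j);
      P(i, j) = v > 0 ? v : 0.0;
    }
}

// cherry table: T(s, k) = P_a(s, x1_k) * P_b(s, x2_k), missing tip => 1
static void cherry_table(const mat& Pa, const mat& Pb, const imat& pairs,
                         mat& T) {
  int np = pairs.n_cols;
  T.set_size(NS, np);
  for (int k = 0; k < np; ++k) {
    int xa = pairs(0, k), xb = pairs(1, k);
    double* tc = T.colptr(k);
    if (xa < MISS && xb < MISS) {
      const double* ca = Pa.colptr(xa);
      const double* cb = Pb.colptr(xb);
      for (int s = 0; s < NS; ++s) tc[s] = ca[s] * cb[s];
    } else if (xa < MISS) {
      const double* ca = Pa.colptr(xa);
      for (int s = 0; s < NS; ++s) tc[s] = ca[s];
    } else if (xb < MISS) {
      const double* cb = Pb.colptr(xb);
      for (int s = 0; s < NS; ++s) tc[s] = cb[s];
    } else {
      for (int s = 0; s < NS; ++s) tc[s] = 1.0;
    }
  }
}

// root combination: fp(p) = sum_s pi(s) A1(s,c1) A2(s,c2) P4(s,xo)
static double root_lnL(const Engine& e, const mat& A1, const mat& A2,
                       const mat& P4, vec* fp_out) {
  double lnL = 0.0;
  vec fp(e.npat);
  for (int p = 0; p < e.npat; ++p) {
    if (e.w(p) == 0.0 && !fp_out) { fp(p) = 1.0; continue; }
    const double* a1 = A1.colptr(e.c1(p));
    const double* a2 = A2.colptr(e.c2(p));
    double f = 0.0;
    int x = e.xo(p);
    if (x < MISS) {
      const double* po = P4.colptr(x);
      for (int s = 0; s < NS; ++s)
        f += e.pi(s) * a1[s] * a2[s] * po[s];
    } else {
      for (int s = 0; s < NS; ++s)
        f += e.pi(s) * a1[s] * a2[s];
    }
    if (f < 1e-300) f = 1e-300;
    fp(p) = f;
    if (e.w(p) != 0.0) lnL += e.w(p) * std::log(f);
  }
  if (fp_out) *fp_out = fp;
  return lnL;
}

// full evaluation; when commit is true the per-branch caches are stored
static double eval_par(Engine& e, const vec& lpar, bool commit) {
  vec t = exp(lpar.subvec(0, 6));
  vec om = exp(lpar.subvec(7, 13));
  double kappa = std::exp(lpar(14));
  mat V[7]; vec lam[7]; double r[7]; mat P[7];
  for (int b = 0; b < 7; ++b) {
    eig_branch(e, kappa, om(b), V[b], lam[b], r[b]);
    pmat_from_eig(e, V[b], lam[b], t(b), P[b]);
  }
  mat T1, T2;
  cherry_table(P[0], P[1], e.pairs1, T1);
  cherry_table(P[2], P[3], e.pairs2, T2);
  mat A1 = P[5] * T1;
  mat A2 = P[6] * T2;
  vec fp;
  double lnL = root_lnL(e, A1, A2, P[4], commit ? &fp : nullptr);
  if (commit) {
    for (int b = 0; b < 7; ++b) {
      e.V[b] = V[b]; e.lam[b] = lam[b]; e.rate[b] = r[b]; e.P[b] = P[b];
    }
    e.T1 = T1; e.T2 = T2; e.A1 = A1; e.A2 = A2; e.fp = fp;
    e.lnL = lnL; e.lastpar = lpar; e.committed = true;
  }
  return lnL;
}

static void ensure_committed(Engine& e, const vec& lpar) {
  if (!e.committed || e.lastpar.n_elem != lpar.n_elem ||
      any(e.lastpar != lpar))
    eval_par(e, lpar, true);
}

// ---- analytic gradient -----------------------------------------------------
//
// dlnL/dP_b is accumulated as a 61 x m "G matrix" for each branch, then
// contracted against dP_b/dtheta via the eigendecomposition:
//   P_b = D^{-1/2} V e^{Lambda t} V' D^{1/2}
//   <G, dP/dt>      = sum_i H_ii lambda_i e^{lambda_i t}
//   <G, dP/dtheta>  = sum_ij H_ij (V' dS V)_ij F_ij     (theta = omega, kappa)
// with H = V' D^{-1/2} G D^{1/2} V and F the divided-difference kernel.

static mat divided_diff(const vec& lam, double t) {
  mat F(NS, NS);
  vec el = exp(lam * t);
  for (int j = 0; j < NS; ++j)
    for (int i = 0; i < NS; ++i) {
      double d = lam(i) - lam(j);
      F(i, j) = (std::abs(d) < 1e-10) ? t * el(i) : (el(i) - el(j)) / d;
    }
  return F;
}

static mat H_of(const Engine& e, const mat& G, const mat& V) {
  // V' D^{-1/2} G D^{1/2} V
  mat M = G;
  for (int j = 0; j < NS; ++j)
    for (int i = 0; i < NS; ++i)
      M(i, j) = e.isqp(i) * G(i, j) * e.sqp(j);
  return V.t() * M * V;
}

// [[Rcpp::export]]
Rcpp::NumericVector eng_grad(SEXP ep, Rcpp::NumericVector lpar_) {
  Rcpp::XPtr<Engine> eptr(ep);
  Engine& e = *eptr;
  vec lpar = as<vec>(lpar_);
  ensure_committed(e, lpar);
  vec t = exp(lpar.subvec(0, 6));
  vec om = exp(lpar.subvec(7, 13));
  double kappa = std::exp(lpar(14));

  // accumulation passes over patterns
  mat W1(NS, e.np1, fill::zeros), W2(NS, e.np2, fill::zeros);
  mat G4(NS, NS, fill::zeros);
  bool any_out_missing = false;
  for (int p = 0; p < e.npat; ++p) {
    if (e.w(p) == 0.0) continue;
    double wf = e.w(p) / e.fp(p);
    const double* a1 = e.A1.colptr(e.c1(p));
    const double* a2 = e.A2.colptr(e.c2(p));
    int x = e.xo(p);
    double* w1 = W1.colptr(e.c1(p));
    double* w2 = W2.colptr(e.c2(p));
    if (x < MISS) {
      const double* po = e.P[4].colptr(x);
      double* g4 = G4.colptr(x);
      for (int s = 0; s < NS; ++s) {
        double pa1 = e.pi(s) * a1[s];
        double pa2 = e.pi(s) * a2[s];
        w1[s] += wf * pa2 * po[s];
        w2[s] += wf * pa1 * po[s];
        g4[s] += wf * pa1 * a2[s];
      }
    } else {
      any_out_missing = true;
      for (int s = 0; s < NS; ++s) {
        w1[s] += wf * e.pi(s) * a2[s];
        w2[s] += wf * e.pi(s) * a1[s];
      }
    }
  }
  (void)any_out_missing;

  // G matrices per branch
  mat G[7];
  G[5] = W1 * e.T1.t();
  G[6] = W2 * e.T2.t();
  G[4] = G4;
  mat B1 = e.P[5].t() * W1;       // 61 x np1
  mat B2 = e.P[6].t() * W2;
  G[0].zeros(NS, NS); G[1].zeros(NS, NS);
  for (int k = 0; k < e.np1; ++k) {
    int x0 = e.pairs1(0, k), x1 = e.pairs1(1, k);
    const double* b = B1.colptr(k);
    if (x0 < MISS) {
      double* g = G[0].colptr(x0);
      if (x1 < MISS) {
        const double* p1 = e.P[1].colptr(x1);
        for (int s = 0; s < NS; ++s) g[s] += b[s] * p1[s];
      } else {
        for (int s = 0; s < NS; ++s) g[s] += b[s];
      }
    }
    if (x1 < MISS) {
      double* g = G[1].colptr(x1);
      if (x0 < MISS) {
        const double* p0 = e.P[0].colptr(x0);
        for (int s = 0; s < NS; ++s) g[s] += b[s] * p0[s];
      } else {
        for (int s = 0; s < NS; ++s) g[s] += b[s];
      }
    }
  }
  G[2].zeros(NS, NS); G[3].zeros(NS, NS);
  for (int k = 0; k < e.np2; ++k) {
    int x2 = e.pairs2(0, k), x3 = e.pairs2(1, k);
    const double* b = B2.colptr(k);
    if (x2 < MISS) {
      double* g = G[2].colptr(x2);
      if (x3 < MISS) {
        const double* p3 = e.P[3].colptr(x3);
        for (int s = 0; s < NS; ++s) g[s] += b[s] * p3[s];
      } else {
        for (int s = 0; s < NS; ++s) g[s] += b[s];
      }
    }
    if (x3 < MISS) {
      double* g = G[3].colptr(x3);
      if (x2 < MISS) {
        const double* p2 = e.P[2].colptr(x2);
        for (int s = 0; s < NS; ++s) g[s] += b[s] * p2[s];
      } else {
        for (int s = 0; s < NS; ++s) g[s] += b[s];
      }
    }
  }

  // contract against dP/dtheta
  Rcpp::NumericVector grad(15);
  mat Sn = e.SC + kappa * e.SD;       // d S_u / d omega
  double rn = e.rC + kappa * e.rD;
  double gkappa = 0.0;
  for (int b = 0; b < 7; ++b) {
    const mat& V = e.V[b];
    const vec& lam = e.lam[b];
    double r = e.rate[b];
    mat H = H_of(e, G[b], V);
    // t (log scale)
    double gt = 0.0;
    for (int i = 0; i < NS; ++i)
      gt += H(i, i) * lam(i) * std::exp(lam(i) * t(b));
    grad[b] = gt * t(b);
    mat F = divided_diff(lam, t(b));
    // omega (log scale)
    mat Vn = V.t() * Sn * V;
    double go = 0.0;
    for (int j = 0; j < NS; ++j)
      for (int i = 0; i < NS; ++i)
        go += H(i, j) * F(i, j) *
          (Vn(i, j) / r - (i == j ? (rn / r) * lam(i) : 0.0));
    // note: the -S*rn/r term is diagonal in the eigenbasis: V'SV = Lambda
    grad[7 + b] = go * om(b);
    // kappa contribution of this branch
    mat Sk = e.SB + om(b) * e.SD;
    double rk = e.rB + om(b) * e.rD;
    mat Vk = V.t() * Sk * V;
    double gk = 0.0;
    for (int j = 0; j < NS; ++j)
      for (int i = 0; i < NS; ++i)
        gk += H(i, j) * F(i, j) *
          (Vk(i, j) / r - (i == j ? (rk / r) * lam(i) : 0.0));
    gkappa += gk;
  }
  grad[14] = gkappa * kappa;
  return grad;
}

// numeric forward-difference gradient (cross-check / fallback)
// [[Rcpp::export]]
Rcpp::NumericVector eng_grad_fd(SEXP ep, Rcpp::NumericVector lpar_,
                                double h) {
  Rcpp::XPtr<Engine> eptr(ep);
  Engine& e = *eptr;
  vec lpar = as<vec>(lpar_);
  ensure_committed(e, lpar);
  double f0 = e.lnL;
  Rcpp::NumericVector g(15);
  for (int j = 0; j < 15; ++j) {
    vec lp = lpar;
    lp(j) += h;
    g[j] = (eval_par(e, lp, false) - f0) / h;
  }
  // restore committed caches
  eval_par(e, lpar, true);
  return g;
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export]]
SEXP eng_create(Rcpp::IntegerMatrix pat, Rcpp::NumericVector w,
                Rcpp::NumericVector pi61, Rcpp::NumericMatrix bf,
                Rcpp::IntegerMatrix cls) {
  Engine* e = new Engine();
  int npat = pat.ncol();
  e->npat = npat;
  e->pat.set_size(5, npat);
  for (int p = 0; p < npat; ++p)
    for (int i = 0; i < 5; ++i) e->pat(i, p) = pat(i, p);
  e->w = as<vec>(w);
  e->pi = as<vec>(pi61);
  e->sqp = sqrt(e->pi);
  e->isqp = 1.0 / e->sqp;
  // generator components: class 1 syn tv (A), 2 syn ts (B),
  // 3 nonsyn tv (C), 4 nonsyn ts (D)
  mat BF = Rcpp::as<arma::mat>(bf);
  mat Q[5];
  for (int c = 1; c <= 4; ++c) Q[c].zeros(NS, NS);
  for (int j = 0; j < NS; ++j)
    for (int i = 0; i < NS; ++i) {
      int c = cls(i, j);
      if (c >= 1) Q[c](i, j) = BF(i, j);
    }
  double rr[5];
  mat* SS[5] = {nullptr, &e->SA, &e->SB, &e->SC, &e->SD};
  for (int c = 1; c <= 4; ++c) {
    vec rs = sum(Q[c], 1);
    Q[c].diag() = -rs;
    rr[c] = dot(e->pi, rs);
    mat& S = *SS[c];
    S.set_size(NS, NS);
    for (int j = 0; j < NS; ++j)
      for (int i = 0; i < NS; ++i)
        S(i, j) = e->sqp(i) * Q[c](i, j) * e->isqp(j);
    S = 0.5 * (S + S.t());
  }
  e->rA = rr[1]; e->rB = rr[2]; e->rC = rr[3]; e->rD = rr[4];
  // unique cherry pairs
  std::map<std::pair<int,int>, int> m1, m2;
  e->c1.set_size(npat); e->c2.set_size(npat); e->xo.set_size(npat);
  std::vector<std::pair<int,int>> v1, v2;
  for (int p = 0; p < npat; ++p) {
    std::pair<int,int> k1(e->pat(0, p), e->pat(1, p));
    std::pair<int,int> k2(e->pat(2, p), e->pat(3, p));
    if (m1.find(k1) == m1.end()) { m1[k1] = v1.size(); v1.push_back(k1); }
    if (m2.find(k2) == m2.end()) { m2[k2] = v2.size(); v2.push_back(k2); }
    e->c1(p) = m1[k1]; e->c2(p) = m2[k2]; e->xo(p) = e->pat(4, p);
  }
  e->np1 = v1.size(); e->np2 = v2.size();
  e->pairs1.set_size(2, e->np1);
  for (int k = 0; k < e->np1; ++k) {
    e->pairs1(0, k) = v1[k].first; e->pairs1(1, k) = v1[k].second;
  }
  e->pairs2.set_size(2, e->np2);
  for (int k = 0; k < e->np2; ++k) {
    e->pairs2(0, k) = v2[k].first; e->pairs2(1, k) = v2[k].second;
  }
  Rcpp::XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void eng_set_weights(SEXP ep, Rcpp::NumericVector w) {
  Rcpp::XPtr<Engine> e(ep);
  e->w = as<vec>(w);
  e->committed = false;
}

// [[Rcpp::export]]
double eng_loglik(SEXP ep, Rcpp::NumericVector lpar) {
  Rcpp::XPtr<Engine> e(ep);
  return eval_par(*e, as<vec>(lpar), true);
}

// [[Rcpp::export]]
Rcpp::NumericVector eng_site_loglik(SEXP ep, Rcpp::NumericVector lpar) {
  Rcpp::XPtr<Engine> e(ep);
  vec lp = as<vec>(lpar);
  eval_par(*e, lp, true);
  Rcpp::NumericVector out(e->npat);
  for (int p = 0; p < e->npat; ++p) out[p] = std::log(e->fp(p));
  return out;
}

// Marginal posterior codon distributions at the three internal nodes
// (n1 = paternal ancestral, n2 = maternal ancestral, n3 = root), per pattern.
// [[Rcpp::export]]
Rcpp::List eng_posterior(SEXP ep, Rcpp::NumericVector lpar) {
  Rcpp::XPtr<Engine> e(ep);
  vec lp = as<vec>(lpar);
  eval_par(*e, lp, true);
  int npat = e->npat;
  mat post1(NS, npat), post2(NS, npat), post3(NS, npat);
  vec b3(NS), b1(NS), b2(NS), tmp(NS);
  for (int p = 0; p < npat; ++p) {
    const double* a1 = e->A1.colptr(e->c1(p));
    const double* a2 = e->A2.colptr(e->c2(p));
    int x = e->xo(p);
    double f = 0.0;
    for (int s = 0; s < NS; ++s) {
      double po = (x < MISS) ? e->P[4](s, x) : 1.0;
      b3(s) = e->pi(s) * po;
      double v = b3(s) * a1[s] * a2[s];
      post3(s, p) = v;
      f += v;
    }
    post3.col(p) /= f;
    for (int s = 0; s < NS; ++s) tmp(s) = b3(s) * a2[s];
    b1 = e->P[5].t() * tmp;
    const double* t1 = e->T1.colptr(e->c1(p));
    double f1 = 0.0;
    for (int s = 0; s < NS; ++s) {
      double v = b1(s) * t1[s]; post1(s, p) = v; f1 += v;
    }
    post1.col(p) /= f1;
    for (int s = 0; s < NS; ++s) tmp(s) = b3(s) * a1[s];
    b2 = e->P[6].t() * tmp;
    const double* t2 = e->T2.colptr(e->c2(p));
    double f2 = 0.0;
    for (int s = 0; s < NS; ++s) {
      double v = b2(s) * t2[s]; post2(s, p) = v; f2 += v;
    }
    post2.col(p) /= f2;
  }
  return Rcpp::List::create(
    Rcpp::Named("paternal_ancestral") = post1,
    Rcpp::Named("maternal_ancestral") = post2,
    Rcpp::Named("root") = post3);
}

// Transition probability matrix for one branch (used by the simulator and
// by small-scale oracles).
// [[Rcpp::export]]
Rcpp::NumericMatrix codon_pmatrix_cpp(double kappa, double omega, double t,
                                      Rcpp::NumericVector pi61,
                                      Rcpp::NumericMatrix bf,
                                      Rcpp::IntegerMatrix cls) {
  Rcpp::IntegerMatrix dummy(5, 1);
  dummy.fill(MISS);
  Rcpp::NumericVector w1(1, 1.0);
  SEXP ep = eng_create(dummy, w1, pi61, bf, cls);
  Rcpp::XPtr<Engine> e(ep);
  mat V; vec lam; double r;
  eig_branch(*e, kappa, omega, V, lam, r);
  mat P;
  pmat_from_eig(*e, V, lam, t, P);
  for (int i = 0; i < NS; ++i) {
    double s = 0;
    for (int j = 0; j < NS; ++j) s += P(i, j);
    for (int j = 0; j < NS; ++j) P(i, j) /= s;
  }
  return Rcpp::wrap(P);
}
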