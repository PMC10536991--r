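// Compiled numerical core: SCC Coulomb kernel, self-consistent-field solver,
// and the forward/adjoint evaluation used during gradient training.
//
// The training loss depends on the density matrix P obtained from the
// generalized eigenproblem H C = S C e (Loewdin orthogonalization,
// Q = S^{-1/2}).  Reverse-mode derivatives are propagated analytically:
// through the occupied/virtual rotation of the eigenvectors, through Q via
// the eigendecomposition of S, and through the charge-shift term of the
// Fock matrix.  Charge fluctuations entering the Fock operator are frozen
// between SCF refreshes (loop inversion), so no derivative flows through
// the SCF fixed point itself.

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// ---------------------------------------------------------------------------
// Coulomb kernel for exponentially decaying s-like charge densities with
// decay tau = (16/5) U per shell: gamma(R) = 1/R - s(ta, tb, R).
// A series in the asymmetry e = (ta-tb)/(ta+tb) keeps the evaluation stable
// when the decays nearly coincide.

static double short_range_term(double ta, double tb, double R) {
  double t = 0.5 * (ta + tb);
  double e = (ta - tb) / (ta + tb);
  double x = t * R;
  if (std::fabs(e) < 0.05) {
    double x2 = x * x, x3 = x2 * x, x4 = x3 * x, x5 = x4 * x, x6 = x5 * x,
           x7 = x6 * x, x8 = x7 * x;
    double c0 = (x3 + 9.0 * x2 + 33.0 * x + 48.0) / (48.0 * R);
    double c2 = t * (x4 + 15.0 * x3 + 75.0 * x2 + 180.0 * x + 180.0) / 480.0;
    double c4 = t * (x6 + 21.0 * x5 + 133.0 * x4 + 280.0 * x3
                     - 840.0 * x - 840.0) / 13440.0;
    double c6 = t * (x8 + 27.0 * x7 + 207.0 * x6 + 252.0 * x5 - 2268.0 * x4
                     - 7560.0 * x3 - 7560.0 * x2) / 725760.0;
    double e2 = e * e;
    return std::exp(-x) * (c0 + e2 * (c2 + e2 * (c4 + e2 * c6)));
  }
  double ta2 = ta * ta, tb2 = tb * tb;
  double d = ta2 - tb2;
  double fa = (tb2 * tb2 * ta) / (2.0 * d * d)
            - (tb2 * tb2 * tb2 - 3.0 * tb2 * tb2 * ta2) / (d * d * d * R);
  double fb = (ta2 * ta2 * tb) / (2.0 * d * d)
            + (ta2 * ta2 * ta2 - 3.0 * ta2 * ta2 * tb2) / (d * d * d * R);
  return std::exp(-ta * R) * fa + std::exp(-tb * R) * fb;
}

static double gamma_onsite(double ta, double tb) {
  double s = ta + tb;
  return ta * tb * (ta * ta + 3.0 * ta * tb + tb * tb) / (2.0 * s * s * s);
}

static double gamma_pair(double ta, double tb, double R) {
  if (R < 1e-9) return gamma_onsite(ta, tb);
  return 1.0 / R - short_range_term(ta, tb, R);
}

// [[Rcpp::export]]
NumericMatrix cpp_gamma_matrix(NumericVector hubbard, NumericMatrix R_bohr) {
  int n = hubbard.size();
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i) {
    double ti = 3.2 * hubbard[i];
    for (int j = i; j < n; ++j) {
      double tj = 3.2 * hubbard[j];
      double g = gamma_pair(ti, tj, R_bohr(i, j));
      G(i, j) = g;
      G(j, i) = g;
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Assembly of H1 and S from the precomputed sparse coefficient maps.
// Entries are linear in the flat parameter vector x.

static void assemble_from_maps(const List& mol, const vec& x, mat& H1, mat& S) {
  int norb = as<int>(mol["norb"]);
  IntegerVector h1i = mol["h1_i"], h1j = mol["h1_j"];
  IntegerVector h1te = mol["h1_te"], h1tp = mol["h1_tp"];
  NumericVector h1tv = mol["h1_tv"];
  IntegerVector si = mol["s_i"], sj = mol["s_j"];
  IntegerVector ste = mol["s_te"], stp = mol["s_tp"];
  NumericVector stv = mol["s_tv"];

  H1.zeros(norb, norb);
  S.eye(norb, norb);
  {
    vec ev(h1i.size(), fill::zeros);
    for (int k = 0; k < h1te.size(); ++k) ev[h1te[k]] += h1tv[k] * x[h1tp[k]];
    for (int e = 0; e < h1i.size(); ++e) {
      H1(h1i[e], h1j[e]) = ev[e];
      H1(h1j[e], h1i[e]) = ev[e];
    }
  }
  {
    vec ev(si.size(), fill::zeros);
    for (int k = 0; k < ste.size(); ++k) ev[ste[k]] += stv[k] * x[stp[k]];
    for (int e = 0; e < si.size(); ++e) {
      S(si[e], sj[e]) = ev[e];
      S(sj[e], si[e]) = ev[e];
    }
  }
}

// [[Rcpp::export]]
List cpp_assemble(List mol, NumericVector x_) {
  vec x(x_.begin(), x_.size());
  mat H1, S;
  assemble_from_maps(mol, x, H1, S);
  return List::create(_["H1"] = H1, _["S"] = S);
}

static mat gamma_from_mol(const List& mol, const vec& x, int perturb_par,
                          double h) {
  IntegerVector shub = mol["shell_hub"];
  NumericMatrix Rsh = mol["Rsh"];
  int ns = shub.size();
  vec tau(ns);
  for (int s = 0; s < ns; ++s) {
    double U = x[shub[s]];
    if (shub[s] == perturb_par) U += h;
    tau[s] = 3.2 * U;
  }
  mat G(ns, ns);
  for (int i = 0; i < ns; ++i)
    for (int j = i; j < ns; ++j) {
      double g = gamma_pair(tau[i], tau[j], Rsh(i, j));
      G(i, j) = g;
      G(j, i) = g;
    }
  return G;
}

// ---------------------------------------------------------------------------
// SCF core on raw matrices.  Linear mixing with Anderson acceleration on the
// charge-fluctuation vector.  Returns a flagged (not thrown) result on
// non-convergence; throws only on structural failures (S not positive
// definite, fractional frontier occupancy).

struct ScfOut {
  vec dq, pop, eps;
  mat P;
  double e1, e2;
  bool converged;
  int niter;
};

static void scf_core(const mat& H1, const mat& S, const mat& G,
                     const uvec& orb_shell, const vec& q0, int nocc,
                     double tol, int max_iter, double mix, int anderson_depth,
                     int anderson_start, ScfOut& out) {
  int n = H1.n_rows;
  int ns = q0.n_elem;
  vec seval;
  mat sevec;
  if (!eig_sym(seval, sevec, S)) stop("overlap eigendecomposition failed");
  if (seval.min() < 1e-8) stop("overlap matrix not positive definite");
  mat Q = sevec * diagmat(1.0 / sqrt(seval)) * sevec.t();

  bool gamma_zero = (G.n_elem == 0) || (abs(G).max() == 0.0);
  vec dq(ns, fill::zeros);
  std::deque<vec> xs, fs;

  out.converged = false;
  for (int it = 1; it <= max_iter; ++it) {
    vec shift = gamma_zero ? vec(ns, fill::zeros) : vec(G * dq);
    vec shorb(n);
    for (int o = 0; o < n; ++o) shorb[o] = shift[orb_shell[o]];
    mat H = H1 + S % (0.5 * (repmat(shorb, 1, n) + repmat(shorb.t(), n, 1)));
    vec ee;
    mat V;
    if (!eig_sym(ee, V, Q * H * Q)) stop("eigendecomposition failed");
    if (nocc > 0 && nocc < n && ee(nocc) - ee(nocc - 1) < 1e-9)
      stop("degenerate frontier orbitals: fractional occupancy not supported (closed-shell aufbau filling)");
    mat C = Q * V.cols(0, nocc - 1);
    mat P = 2.0 * C * C.t();
    vec pop_orb = sum(P % S, 1);
    vec pop(ns, fill::zeros);
    for (int o = 0; o < n; ++o) pop[orb_shell[o]] += pop_orb[o];
    vec dq_new = pop - q0;
    double err = ns ? abs(dq_new - dq).max() : 0.0;

    out.dq = dq;  // charges the current density was built from
    out.pop = pop;
    out.P = P;
    out.eps = ee;
    out.e1 = accu(P % H1);
    out.niter = it;
    if (err < tol || gamma_zero) {
      out.dq = dq_new;
      out.converged = true;
      break;
    }
    // Anderson acceleration on the fixed-point residual f = g(dq) - dq
    vec f = dq_new - dq;
    vec dq_next;
    if (it >= anderson_start && (int)xs.size() >= 1) {
      int m = std::min<int>(anderson_depth, xs.size());
      mat dF(ns, m), dX(ns, m);
      for (int j = 0; j < m; ++j) {
        dF.col(j) = f - fs[fs.size() - 1 - j];
        dX.col(j) = dq - xs[xs.size() - 1 - j];
      }
      mat AtA = dF.t() * dF;
      AtA.diag() += 1e-12 * (trace(AtA) + 1e-30);
      vec theta;
      bool ok = solve(theta, AtA, dF.t() * f, solve_opts::no_approx);
      if (ok) {
        dq_next = (dq - dX * theta) + mix * (f - dF * theta);
      } else {
        dq_next = dq + mix * f;
      }
    } else {
      dq_next = dq + mix * f;
    }
    xs.push_back(dq);
    fs.push_back(f);
    while ((int)xs.size() > anderson_depth + 1) { xs.pop_front(); fs.pop_front(); }
    dq = dq_next;
  }
  if (!out.converged) out.dq = out.pop - q0;
  out.e2 = gamma_zero ? 0.0 : 0.5 * dot(out.dq, G * out.dq);
}

// [[Rcpp::export]]
List cpp_scf_raw(arma::mat H1, arma::mat S, arma::mat G,
                 IntegerVector orb_shell, NumericVector shell_q0,
                 int nocc, List opts) {
  int n = H1.n_rows;
  uvec osh(n);
  for (int o = 0; o < n; ++o) osh[o] = orb_shell[o];
  vec q0(shell_q0.begin(), shell_q0.size());
  ScfOut out;
  scf_core(H1, S, G, osh, q0, nocc,
           as<double>(opts["tol"]), as<int>(opts["max_iter"]),
           as<double>(opts["mixing"]), as<int>(opts["anderson_depth"]),
           as<int>(opts["anderson_start"]), out);
  return List::create(
    _["dq"] = out.dq, _["populations"] = out.pop, _["P"] = out.P,
    _["mo_energies"] = out.eps, _["e_band_structure"] = out.e1,
    _["e_coulomb"] = out.e2, _["converged"] = out.converged,
    _["n_iterations"] = out.niter);
}

// Full SCF for a precomputed molecule: assemble from maps, build gamma from
// the Hubbard entries of x, solve, and report predictions.
// [[Rcpp::export]]
List cpp_scf_mol(List mol, NumericVector x_, List opts) {
  vec x(x_.begin(), x_.size());
  mat H1, S;
  assemble_from_maps(mol, x, H1, S);
  mat G = gamma_from_mol(mol, x, -1, 0.0);
  IntegerVector orb_shell = mol["orb_shell"];
  IntegerVector shell_atom = mol["shell_atom"];
  NumericVector q0_ = mol["shell_q0"];
  NumericMatrix xyz = mol["xyz"];
  int n = H1.n_rows, ns = q0_.size();
  int natom = xyz.nrow();
  uvec osh(n);
  for (int o = 0; o < n; ++o) osh[o] = orb_shell[o];
  vec q0(q0_.begin(), ns);
  ScfOut out;
  bool ok = true;
  std::string err = "";
  try {
    scf_core(H1, S, G, osh, q0, as<int>(mol["nocc"]),
             as<double>(opts["tol"]), as<int>(opts["max_iter"]),
             as<double>(opts["mixing"]), as<int>(opts["anderson_depth"]),
             as<int>(opts["anderson_start"]), out);
  } catch (std::exception& e) {
    ok = false;
    err = e.what();
  }
  if (!ok) {
    return List::create(_["ok"] = false, _["error"] = err);
  }
  vec q_atom(natom, fill::zeros);
  for (int s = 0; s < ns; ++s) q_atom[shell_atom[s]] -= out.dq[s];
  vec dip(3, fill::zeros);
  for (int a = 0; a < natom; ++a)
    for (int k = 0; k < 3; ++k) dip[k] += q_atom[a] * xyz(a, k);
  return List::create(
    _["ok"] = true, _["dq"] = out.dq, _["q_atom"] = q_atom,
    _["dipole"] = dip, _["e1"] = out.e1, _["e2"] = out.e2,
    _["e_electronic"] = out.e1 + out.e2,
    _["mo_energies"] = out.eps,
    _["converged"] = out.converged, _["n_iterations"] = out.niter);
}

// ---------------------------------------------------------------------------
// Forward + adjoint evaluation of one molecule with frozen charge
// fluctuations.  Accumulates weighted squared residuals and, if requested,
// the gradient with respect to the flat parameter vector.

struct LossAcc {
  double e = 0, d = 0, q = 0;  // weighted squared-error sums (normalized)
  int n_skipped = 0;
};

static void mol_loss_grad(const List& mol, const vec& dq_frozen,
                          double erep_ref, const vec& x, const List& wts,
                          bool want_grad, vec& grad, LossAcc& acc) {
  int norb = as<int>(mol["norb"]);
  int nocc = as<int>(mol["nocc"]);
  double nheavy = as<double>(mol["nheavy"]);
  IntegerVector orb_shell = mol["orb_shell"];
  IntegerVector shell_atom = mol["shell_atom"];
  NumericVector q0_ = mol["shell_q0"];
  NumericMatrix xyz = mol["xyz"];
  int ns = q0_.size(), natom = xyz.nrow();

  double wE2 = as<double>(wts["w_energy"]); wE2 *= wE2;
  double wD2 = as<double>(wts["w_dipole"]); wD2 *= wD2;
  double wQ2 = as<double>(wts["w_charge"]); wQ2 *= wQ2;
  bool per_heavy = as<bool>(wts["per_heavy"]);
  double inv_ne = as<double>(wts["inv_n_energy"]);
  double inv_nd = as<double>(wts["inv_n_dipole"]);
  double inv_nq = as<double>(wts["inv_n_charge"]);

  bool have_E = R_finite(as<double>(mol["t_energy"]));
  bool have_D = mol.containsElementNamed("t_dipole") &&
                !Rf_isNull(mol["t_dipole"]);
  bool have_Q = mol.containsElementNamed("t_charges") &&
                !Rf_isNull(mol["t_charges"]);

  mat H1, S;
  assemble_from_maps(mol, x, H1, S);
  mat G = gamma_from_mol(mol, x, -1, 0.0);

  vec shift = G * dq_frozen;
  vec shorb(norb);
  for (int o = 0; o < norb; ++o) shorb[o] = shift[orb_shell[o]];
  mat sh2 = 0.5 * (repmat(shorb, 1, norb) + repmat(shorb.t(), norb, 1));
  mat Hsc = H1 + S % sh2;

  vec seval;
  mat U;
  if (!eig_sym(seval, U, S)) stop("overlap eigendecomposition failed");
  if (seval.min() < 1e-8) { acc.n_skipped++; return; }
  mat Q = U * diagmat(1.0 / sqrt(seval)) * U.t();

  vec ee;
  mat V;
  if (!eig_sym(ee, V, Q * Hsc * Q)) stop("eigendecomposition failed");
  if (nocc > 0 && nocc < norb && ee(nocc) - ee(nocc - 1) < 1e-9) {
    acc.n_skipped++;
    return;
  }
  mat Vo = V.cols(0, nocc - 1);
  mat Cq = Q * Vo;
  mat P = 2.0 * Cq * Cq.t();

  vec pop_orb = sum(P % S, 1);
  vec pop(ns, fill::zeros);
  for (int o = 0; o < norb; ++o) pop[orb_shell[o]] += pop_orb[o];
  vec dq_pred = pop;
  for (int s = 0; s < ns; ++s) dq_pred[s] -= q0_[s];
  vec q_atom(natom, fill::zeros);
  for (int s = 0; s < ns; ++s) q_atom[shell_atom[s]] -= dq_pred[s];
  vec dip(3, fill::zeros);
  for (int a = 0; a < natom; ++a)
    for (int k = 0; k < 3; ++k) dip[k] += q_atom[a] * xyz(a, k);

  double E1 = accu(P % H1);
  double E2 = 0.5 * dot(dq_frozen, shift);
  double E = E1 + E2 + erep_ref;

  double hn_inv = per_heavy ? 1.0 / std::max(nheavy, 1.0) : 1.0;
  double re = 0;
  vec rd(3, fill::zeros), rq(natom, fill::zeros);
  if (have_E) {
    re = (E - as<double>(mol["t_energy"])) * hn_inv;
    acc.e += inv_ne * wE2 * re * re;
  }
  if (have_D) {
    NumericVector td = mol["t_dipole"];
    for (int k = 0; k < 3; ++k) rd[k] = dip[k] - td[k];
    acc.d += inv_nd * wD2 * dot(rd, rd);
  }
  if (have_Q) {
    NumericVector tq = mol["t_charges"];
    for (int a = 0; a < natom; ++a) rq[a] = q_atom[a] - tq[a];
    acc.q += inv_nq * wQ2 * dot(rq, rq);
  }
  if (!want_grad) return;

  // ---- adjoint seeds
  double Ebar = have_E ? 2.0 * inv_ne * wE2 * re * hn_inv : 0.0;
  vec dipbar = have_D ? vec(2.0 * inv_nd * wD2 * rd) : vec(3, fill::zeros);
  vec qbar = have_Q ? vec(2.0 * inv_nq * wQ2 * rq) : vec(natom, fill::zeros);
  for (int a = 0; a < natom; ++a)
    for (int k = 0; k < 3; ++k) qbar[a] += dipbar[k] * xyz(a, k);
  vec popbar_sh(ns);
  for (int s = 0; s < ns; ++s) popbar_sh[s] = -qbar[shell_atom[s]];
  vec popbar_orb(norb);
  for (int o = 0; o < norb; ++o) popbar_orb[o] = popbar_sh[orb_shell[o]];

  mat popm = 0.5 * (repmat(popbar_orb, 1, norb) + repmat(popbar_orb.t(), norb, 1));
  mat Pbar = Ebar * H1 + S % popm;   // energy trace + Mulliken P-path
  mat Sbar = P % popm;               // Mulliken S-path

  // ---- eigenvector adjoint (occupied-virtual rotations only)
  mat Hpbar(norb, norb, fill::zeros);
  if (nocc < norb) {
    mat Vv = V.cols(nocc, norb - 1);
    mat W = Vv.t() * (4.0 * (Q * Pbar * Q)) * Vo;
    for (int a = 0; a < norb - nocc; ++a)
      for (int i = 0; i < nocc; ++i)
        W(a, i) /= (ee(i) - ee(nocc + a));
    Hpbar = Vv * W * Vo.t();
  }
  mat Hbar = Q * Hpbar * Q;
  mat Po = Vo * Vo.t();
  mat Qbar = Hpbar * Q * Hsc + Hsc * Q * Hpbar
           + 2.0 * (Pbar * Q * Po + Po * Q * Pbar);

  // ---- S^{-1/2} adjoint through the eigendecomposition of S
  {
    mat Qbs = 0.5 * (Qbar + Qbar.t());
    mat Mm = U.t() * Qbs * U;
    mat K(norb, norb);
    for (int i = 0; i < norb; ++i) {
      for (int j = 0; j < norb; ++j) {
        double di = seval[i], dj = seval[j];
        if (std::fabs(di - dj) > 1e-12 * std::max(di, dj)) {
          K(i, j) = (1.0 / std::sqrt(di) - 1.0 / std::sqrt(dj)) / (di - dj);
        } else {
          double dm = 0.5 * (di + dj);
          K(i, j) = -0.5 / (dm * std::sqrt(dm));
        }
      }
    }
    Sbar += U * (Mm % K) * U.t();
  }

  mat Hbs = 0.5 * (Hbar + Hbar.t());
  mat H1bar = Hbs + Ebar * P;
  Sbar += Hbs % sh2;

  // ---- charge-shift and Coulomb-kernel adjoint (Hubbard parameters)
  vec shiftbar_orb = sum(Hbs % S, 1);
  vec shiftbar_sh(ns, fill::zeros);
  for (int o = 0; o < norb; ++o) shiftbar_sh[orb_shell[o]] += shiftbar_orb[o];
  mat Gbar = shiftbar_sh * dq_frozen.t()
           + (0.5 * Ebar) * (dq_frozen * dq_frozen.t());

  IntegerVector shub = mol["shell_hub"];
  std::vector<int> dist;
  for (int s = 0; s < ns; ++s)
    if (std::find(dist.begin(), dist.end(), shub[s]) == dist.end())
      dist.push_back(shub[s]);
  for (int p : dist) {
    double h = 1e-6 * std::max(std::fabs(x[p]), 1e-2);
    mat Gp = gamma_from_mol(mol, x, p, h);
    mat Gm = gamma_from_mol(mol, x, p, -h);
    grad[p] += accu(Gbar % ((Gp - Gm) / (2.0 * h)));
  }

  // ---- scatter matrix adjoints into coefficient gradients
  {
    IntegerVector h1i = mol["h1_i"], h1j = mol["h1_j"];
    IntegerVector h1te = mol["h1_te"], h1tp = mol["h1_tp"];
    NumericVector h1tv = mol["h1_tv"];
    vec ebar(h1i.size());
    for (int e = 0; e < h1i.size(); ++e) {
      ebar[e] = (h1i[e] == h1j[e]) ? H1bar(h1i[e], h1i[e])
                                   : 2.0 * H1bar(h1i[e], h1j[e]);
    }
    for (int k = 0; k < h1te.size(); ++k)
      grad[h1tp[k]] += h1tv[k] * ebar[h1te[k]];
  }
  {
    IntegerVector si = mol["s_i"], sj = mol["s_j"];
    IntegerVector ste = mol["s_te"], stp = mol["s_tp"];
    NumericVector stv = mol["s_tv"];
    vec ebar(si.size());
    for (int e = 0; e < si.size(); ++e)
      ebar[e] = 2.0 * Sbar(si[e], sj[e]);
    for (int k = 0; k < ste.size(); ++k)
      grad[stp[k]] += stv[k] * ebar[ste[k]];
  }
}

// [[Rcpp::export]]
List cpp_batch_loss_grad(List mols, List dqs, NumericVector ereps,
                         LogicalVector skip, NumericVector x_, List wts,
                         bool want_grad) {
  vec x(x_.begin(), x_.size());
  vec grad(x.n_elem, fill::zeros);
  LossAcc acc;
  for (int m = 0; m < mols.size(); ++m) {
    if (skip[m]) { continue; }
    NumericVector dq_ = dqs[m];
    vec dq(dq_.begin(), dq_.size());
    mol_loss_grad(mols[m], dq, ereps[m], x, wts, want_grad, grad, acc);
  }
  return List::create(
    _["loss_energy"] = acc.e, _["loss_dipole"] = acc.d,
    _["loss_charge"] = acc.q, _["loss"] = acc.e + acc.d + acc.q,
    _["grad"] = NumericVector(grad.begin(), grad.end()),
    _["n_skipped"] = acc.n_skipped);
}

// ---------------------------------------------------------------------------
// Regularization penalties on the dense evaluation grid, evaluated in one
// pass over all channels during training.
//   type 0: curvature-sign (convex) penalty, fixed sign
//   type 1: convex penalty with one trainable inflection (smooth blending of
//           the two sign regions with width beta, so the location gradient
//           is well defined)
//   type 2: third-derivative smoothing penalty

// The derivative design matrices of B-splines are banded (at most order
// non-zeros per grid row); descriptors carry the band values `Db`
// (grid_n x bandwidth) plus the 0-based start column `Dstart` per row.

static void band_apply(const mat& Db, const ivec& Dstart, const vec& z,
                       vec& v) {
  int ng = Db.n_rows, bw = Db.n_cols;
  for (int i = 0; i < ng; ++i) {
    double acc = 0.0;
    int s0 = Dstart[i];
    for (int b = 0; b < bw; ++b) acc += Db(i, b) * z[s0 + b];
    v[i] = acc;
  }
}

static void band_scatter(const mat& Db, const ivec& Dstart, const vec& dv,
                         double* g) {
  int ng = Db.n_rows, bw = Db.n_cols;
  for (int i = 0; i < ng; ++i) {
    double d = dv[i];
    if (d == 0.0) continue;
    int s0 = Dstart[i];
    for (int b = 0; b < bw; ++b) g[s0 + b] += Db(i, b) * d;
  }
}

// Bulk evaluation of all fixed-sign (convex) and smoothing penalty rows in
// one pass: rows from every channel are concatenated; `col0` holds the
// global 0-based column of each row's first band entry.
//   mode 0: weight * max(0, -sign * v)^2      (curvature sign)
//   mode 2: weight * v^2                      (third-derivative smoothing)
// [[Rcpp::export]]
List cpp_penalties_bulk(NumericMatrix Vbt_, IntegerVector col0_,
                        IntegerVector mode_, NumericVector weight_,
                        NumericVector sign_, NumericVector x_,
                        bool want_grad) {
  // Vbt: bandwidth x n_rows (transposed so each row's band is contiguous)
  int bw = Vbt_.nrow(), nr = Vbt_.ncol();
  const double* Vb = Vbt_.begin();
  vec x(x_.begin(), x_.size());
  vec grad(x.n_elem, fill::zeros);
  double total = 0.0;
  for (int i = 0; i < nr; ++i) {
    const double* row = Vb + (size_t)i * bw;
    int c0 = col0_[i];
    double v = 0.0;
    for (int b = 0; b < bw; ++b) v += row[b] * x[c0 + b];
    double w = weight_[i];
    double dv = 0.0;
    if (mode_[i] == 2) {
      total += w * v * v;
      dv = 2.0 * w * v;
    } else {
      double u = -sign_[i] * v;
      if (u > 0.0) {
        total += w * u * u;
        dv = -2.0 * w * sign_[i] * u;
      }
    }
    if (want_grad && dv != 0.0)
      for (int b = 0; b < bw; ++b) grad[c0 + b] += row[b] * dv;
  }
  return List::create(_["penalty"] = total,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}

// [[Rcpp::export]]
List cpp_penalties(List pens, NumericVector x_, bool want_grad) {
  vec x(x_.begin(), x_.size());
  vec grad(x.n_elem, fill::zeros);
  double total = 0.0;
  for (int ip = 0; ip < pens.size(); ++ip) {
    List pn = pens[ip];
    int type = as<int>(pn["type"]);
    NumericMatrix Db_ = pn["Db"];
    mat Db(Db_.begin(), Db_.nrow(), Db_.ncol(), false);
    IntegerVector Dstart_ = pn["Dstart"];
    ivec Dstart(Dstart_.begin(), Dstart_.size());
    int off = as<int>(pn["offset"]);
    double wgt = as<double>(pn["weight"]);
    if (wgt <= 0) continue;
    int nf = as<int>(pn["n_free"]);
    vec z = x.subvec(off, off + nf - 1);
    int ng = Db.n_rows;
    vec v(ng);
    band_apply(Db, Dstart, z, v);
    if (type == 2) {
      total += wgt * dot(v, v);
      if (want_grad) band_scatter(Db, Dstart, vec(2.0 * wgt * v),
                                  grad.memptr() + off);
    } else if (type == 0) {
      double s = as<double>(pn["sign"]);
      vec hinge = -s * v;
      hinge.transform([](double u) { return u > 0 ? u : 0.0; });
      total += wgt * dot(hinge, hinge);
      if (want_grad) band_scatter(Db, Dstart, vec(-2.0 * wgt * s * hinge),
                                  grad.memptr() + off);
    } else {
      double s = as<double>(pn["sign"]);  // required sign on the tail side
      NumericVector rg = pn["r_grid"];
      int lat = as<int>(pn["latent"]);
      double beta = as<double>(pn["beta"]);
      double rlo = as<double>(pn["r_low"]), rcu = as<double>(pn["r_cut"]);
      double t = x[lat];
      double sig = 1.0 / (1.0 + std::exp(-t));
      double xi = rlo + (rcu - rlo) * sig;
      vec dv(ng, fill::zeros);
      double dpen_dxi = 0.0;
      double pen = 0.0;
      // tanh-modulated hinge: the required curvature sign flips smoothly at
      // the inflection; the modulation vanishes at the flip point, so a
      // degenerate inflection at r_low reduces to the plain convex penalty
      for (int i = 0; i < ng; ++i) {
        double arg = (rg[i] - xi) / beta;
        double th = (arg > 20.0) ? 1.0 : (arg < -20.0 ? -1.0 : std::tanh(arg));
        double u = std::max(0.0, -s * th * v[i]);
        pen += u * u;
        if (want_grad && u > 0.0) {
          dv[i] = 2.0 * u * (-s * th);
          dpen_dxi += 2.0 * u * (-s * v[i]) * (-(1.0 - th * th) / beta);
        }
      }
      total += wgt * pen;
      if (want_grad) {
        band_scatter(Db, Dstart, vec(wgt * dv), grad.memptr() + off);
        grad[lat] += wgt * dpen_dxi * (rcu - rlo) * sig * (1.0 - sig);
      }
    }
  }
  return List::create(_["penalty"] = total,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}
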