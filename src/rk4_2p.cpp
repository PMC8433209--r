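#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classical RK4 for the two-parameter transport system.
// State: y1 = Vw (um^3), y2 = ns (amount in litre-mole units so that
// ns / Vw is mol/L). Written independently of the adaptive solver path;
// serves as the brute-force reference integrator.

static inline void deriv(double t, double Vw, double ns,
                         double Lp_s, double Ps, double A, double RT,
                         double m_salt_e, double m_cpa, double n_salt,
                         bool step_schedule, double tau,
                         double &dVw, double &dns) {
  double m_cpa_e = step_schedule ? m_cpa
                                 : m_cpa * (1.0 - std::exp(-std::max(t, 0.0) / tau));
  double osm_i = (n_salt + ns) / Vw;
  dVw = -Lp_s * A * RT * ((m_salt_e + m_cpa_e) - osm_i);
  dns = Ps * A * (m_cpa_e - ns / Vw);
}

// [[Rcpp::export]]
NumericMatrix rk4_2p_cpp(NumericVector times, double Vw0, double ns0,
                         double dt, double Lp_s, double Ps, double A,
                         double RT, double m_salt_e, double m_cpa,
                         double n_salt, bool step_schedule, double tau) {
  int n = times.size();
  NumericMatrix out(n, 2);
  double t = times[0], Vw = Vw0, ns = ns0;
  out(0, 0) = Vw; out(0, 1) = ns;
  double k1V, k1n, k2V, k2n, k3V, k3n, k4V, k4n;
  for (int i = 1; i < n; ++i) {
    double t_target = times[i];
    while (t < t_target - 1e-12) {
      double h = std::min(dt, t_target - t);
      deriv(t, Vw, ns, Lp_s, Ps, A, RT, m_salt_e, m_cpa, n_salt,
            step_schedule, tau, k1V, k1n);
      deriv(t + h / 2, Vw + h / 2 * k1V, ns + h / 2 * k1n,
            Lp_s, Ps, A, RT, m_salt_e, m_cpa, n_salt,
            step_schedule, tau, k2V, k2n);
      deriv(t + h / 2, Vw + h / 2 * k2V, ns + h / 2 * k2n,
            Lp_s, Ps, A, RT, m_salt_e, m_cpa, n_salt,
            step_schedule, tau, k3V, k3n);
      deriv(t + h, Vw + h * k3V, ns + h * k3n,
            Lp_s, Ps, A, RT, m_salt_e, m_cpa, n_salt,
            step_schedule, tau, k4V, k4n);
      Vw += h / 6.0 * (k1V + 2 * k2V + 2 * k3V + k4V);
      ns += h / 6.0 * (k1n + 2 * k2n + 2 * k3n + k4n);
      t += h;
    }
    t = t_target;
    out(i, 0) = Vw; out(i, 1) = ns;
  }
  return out;
}
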