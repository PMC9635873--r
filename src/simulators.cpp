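#include <Rcpp.h>
using namespace Rcpp;

// Trial-loop cores for the two learning models. Kept in C++ because the
// multi-start fitter evaluates them hundreds of thousands of times.

// Rescorla-Wagner simulator with a movement-plan CS present on every trial.
// cs codes: 1 = tone, 2 = light, 3 = compound (tone + light).
// us: indicator (1 on 15-degree-clamp trials, 0 otherwise).
// Returns per-trial pre-update associative strengths and the predicted
// heading V_total (plan + CSs present on the trial). The update after trial n
// applies the shared prediction error lam*us[n] - V_total[n] to the plan CS
// and to each element CS present on trial n.
// [[Rcpp::export]]
NumericMatrix rw_sim_cpp(IntegerVector cs, NumericVector us,
                         double alpha_plan, double alpha_tone,
                         double alpha_light, double beta, double lam) {
  int n = cs.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("v_plan", "v_tone", "v_light",
                                          "v_total", "spe");
  double vp = 0.0, vt = 0.0, vl = 0.0;
  for (int i = 0; i < n; i++) {
    bool tone  = cs[i] == 1 || cs[i] == 3;
    bool light = cs[i] == 2 || cs[i] == 3;
    double vtot = vp + (tone ? vt : 0.0) + (light ? vl : 0.0);
    double err = lam * us[i] - vtot;
    out(i, 0) = vp;
    out(i, 1) = vt;
    out(i, 2) = vl;
    out(i, 3) = vtot;
    out(i, 4) = err;
    vp += alpha_plan * beta * err;
    if (tone)  vt += alpha_tone * beta * err;
    if (light) vl += alpha_light * beta * err;
  }
  return out;
}

// Single-process state-space simulator: x[0] = 0,
// x[n] = A * x[n-1] + B * e[n-1], with e the per-trial driving error.
// [[Rcpp::export]]
NumericVector ss_sim_cpp(NumericVector e, double A, double B) {
  int n = e.size();
  NumericVector x(n);
  x[0] = 0.0;
  for (int i = 1; i < n; i++) x[i] = A * x[i - 1] + B * e[i - 1];
  return x;
}

// Sum of squared residuals of the RW prediction against an observed series,
// restricted to valid trials. The model state propagates through all trials.
// [[Rcpp::export]]
double rw_ssr_cpp(IntegerVector cs, NumericVector us, NumericVector obs,
                  LogicalVector valid, double alpha_plan, double alpha_tone,
                  double alpha_light, double beta, double lam) {
  int n = cs.size();
  double vp = 0.0, vt = 0.0, vl = 0.0, ssr = 0.0;
  for (int i = 0; i < n; i++) {
    bool tone  = cs[i] == 1 || cs[i] == 3;
    bool light = cs[i] == 2 || cs[i] == 3;
    double vtot = vp + (tone ? vt : 0.0) + (light ? vl : 0.0);
    if (valid[i]) {
      double r = obs[i] - vtot;
      ssr += r * r;
    }
    double err = lam * us[i] - vtot;
    vp += alpha_plan * beta * err;
    if (tone)  vt += alpha_tone * beta * err;
    if (light) vl += alpha_light * beta * err;
  }
  return ssr;
}

// [[Rcpp::export]]
double ss_ssr_cpp(NumericVector e, NumericVector obs, LogicalVector valid,
                  double A, double B) {
  int n = e.size();
  double x = 0.0, ssr = 0.0;
  for (int i = 0; i < n; i++) {
    if (i > 0) x = A * x + B * e[i - 1];
    if (valid[i]) {
      double r = obs[i] - x;
      ssr += r * r;
    }
  }
  return ssr;
}
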