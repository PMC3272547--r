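#include <Rcpp.h>
using namespace Rcpp;

// von Mises draw via the Best-Fisher (1979) rejection scheme, consuming
// the R random stream; kappa ~ 0 falls back to uniform.
static double rvm1(double mu, double kappa) {
  if (kappa < 1e-9) return mu + R::runif(-M_PI, M_PI);
  const double a = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  const double b = (a - std::sqrt(2.0 * a)) / (2.0 * kappa);
  const double r = (1.0 + b * b) / (2.0 * b);
  for (;;) {
    double u1 = R::runif(0.0, 1.0);
    double u2 = R::runif(0.0, 1.0);
    double u3 = R::runif(0.0, 1.0);
    double z = std::cos(M_PI * u1);
    double f = (1.0 + r * z) / (r + z);
    double c = kappa * (r - f);
    if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
      double fc = std::max(-1.0, std::min(1.0, f));
      double th = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(fc);
      return mu + th;
    }
  }
}

// One update step of the agent-based model. Modifies nothing in place;
// returns the new positions, headings, arrived flags and refractory
// counters. The random draw order is: one direction per exactly
// coincident pair (in (i, j), i < j order), then one von Mises angle
// per agent in index order.
// [[Rcpp::export(name = ".engine_step")]]
List engine_step(NumericMatrix positions, NumericMatrix headings,
                 LogicalVector arrived, IntegerVector refractory,
                 List cfg) {
  const int n = positions.nrow();
  const double speed = as<double>(cfg["speed"]);
  const double dt = as<double>(cfg["dt"]);
  const double r_cil = as<double>(cfg["r_cil"]);
  const double lambda = as<double>(cfg["lambda_coa"]);
  const double w_cil = as<double>(cfg["w_cil"]);
  const double w_coa = as<double>(cfg["w_coa"]);
  const double w_persist = as<double>(cfg["w_persist"]);
  const double kappa0 = as<double>(cfg["noise_kappa"]);
  const int persist_steps = as<int>(cfg["cil_persist_steps"]);
  const double persist_gain = as<double>(cfg["cil_persist_gain"]);
  const double self_excl = as<double>(cfg["self_exclusion_radius"]);
  const std::string arena = as<std::string>(cfg["arena_type"]);
  double aw = 0, al = 0, adepth = 0;
  if (arena == "corridor") {
    aw = as<double>(cfg["arena_width"]);
    al = as<double>(cfg["arena_length"]);
    adepth = as<double>(cfg["arena_target_depth"]);
  }

  NumericMatrix pos = clone(positions);
  NumericMatrix hd = clone(headings);
  LogicalVector arr = clone(arrived);
  IntegerVector refr = clone(refractory);

  const bool need_cil = w_cil > 0 && n > 1;
  const bool need_coa = w_coa > 0 && n > 1;

  std::vector<double> Rx(n, 0.0), Ry(n, 0.0), ghx(n, 0.0), ghy(n, 0.0);
  std::vector<int> contact(n, 0);

  if (need_cil || need_coa) {
    // displaced unit directions for exactly coincident pairs
    std::vector<double> gx(n, 0.0), gy(n, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d == 0.0) {
          double th = R::runif(-M_PI, M_PI);
          dx = std::cos(th);
          dy = std::sin(th);
          d = 1.0;
        }
        bool in_contact = d < r_cil;
        if (in_contact) {
          contact[i] = contact[j] = 1;
          if (need_cil) {
            double ux = dx / d, uy = dy / d;
            Rx[i] += ux; Ry[i] += uy;
            Rx[j] -= ux; Ry[j] -= uy;
          }
        }
        if (need_coa && d > self_excl) {
          double e = std::exp(-d / lambda) / (lambda * d);
          gx[i] -= e * dx; gy[i] -= e * dy;
          gx[j] += e * dx; gy[j] += e * dy;
        }
      }
    }
    if (need_coa) {
      for (int i = 0; i < n; ++i) {
        double gn = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i]);
        if (gn > 0) { ghx[i] = gx[i] / gn; ghy[i] = gy[i] / gn; }
      }
    }
  }

  const double step_len = speed * dt;
  for (int i = 0; i < n; ++i) {
    // refractory bookkeeping runs for every agent (frozen agents keep
    // their counters decaying), but only CIL-carrying runs use it
    if (need_cil && persist_steps > 0) {
      refr[i] = contact[i] ? persist_steps : std::max(refr[i] - 1, 0);
    } else {
      refr[i] = 0;
    }
    double kappa = refr[i] > 0 ? kappa0 * persist_gain : kappa0;
    double old_angle = std::atan2(hd(i, 1), hd(i, 0));
    double na = rvm1(old_angle, kappa);
    if (arr[i]) continue;  // the draw keeps the stream aligned per agent
    double vx = w_persist * hd(i, 0) + std::cos(na) + w_cil * Rx[i] +
      w_coa * ghx[i];
    double vy = w_persist * hd(i, 1) + std::sin(na) + w_cil * Ry[i] +
      w_coa * ghy[i];
    double vn = std::sqrt(vx * vx + vy * vy);
    double nhx, nhy;
    if (vn < 1e-12) { nhx = hd(i, 0); nhy = hd(i, 1); }
    else { nhx = vx / vn; nhy = vy / vn; }
    double x = pos(i, 0) + step_len * nhx;
    double y = pos(i, 1) + step_len * nhy;
    if (arena == "corridor") {
      for (int it = 0; it < 10; ++it) {
        bool moved = false;
        if (x < 0) { x = -x; nhx = -nhx; moved = true; }
        if (x > aw) { x = 2 * aw - x; nhx = -nhx; moved = true; }
        if (y > al) { y = 2 * al - y; nhy = -nhy; moved = true; }
        if (!moved) break;
      }
      if (y <= adepth) { y = adepth; arr[i] = true; }
    }
    pos(i, 0) = x; pos(i, 1) = y;
    hd(i, 0) = nhx; hd(i, 1) = nhy;
  }

  return List::create(_["positions"] = pos, _["headings"] = hd,
                      _["arrived"] = arr, _["refractory"] = refr);
}
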