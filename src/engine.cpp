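// Simulation engine: softmax policy over afterstate values + SARSA-style
// updates for the three agent types, run for a budget of episodes or total
// steps. All randomness comes from R's RNG (unif_rand), so set.seed() on
// the R side makes runs bit-reproducible.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

const int DX[4] = {1, -1, 0, 0};  // east, west, south, north
const int DY[4] = {0, 0, -1, 1};

struct World {
  int width, height;
  LogicalMatrix passable;  // [x-1, y-1]
  int start_x, start_y;
  IntegerMatrix goals;     // n x 2 of (x, y)
  NumericVector goal_rewards;
  double wall_penalty;

  bool pass(int x, int y) const { return passable(x - 1, y - 1); }
  int goal_at(int x, int y) const {
    for (int i = 0; i < goals.nrow(); ++i)
      if (goals(i, 0) == x && goals(i, 1) == y) return i;
    return -1;
  }
};

// Agent state. OVaRLAP carries Mt (n_hidden x n_input, one contiguous
// column per grid square), the channel weights w1/w2 and their cached
// difference wd = w1 - w2 used for value reads.
struct Agent {
  int type = 0;  // 0 = ovarlap, 1 = tabular, 2 = maxpain
  NumericMatrix Mt;
  std::vector<double> w1, w2, wd;
  double alpha1 = 0, alpha2 = 0, gamma = 0;
  int height = 20;
  NumericMatrix v;
  double alpha_s = 0, gamma_s = 0;
  NumericMatrix vr, vp;
  double alpha_r = 0, alpha_p = 0, gamma_r = 0, gamma_p = 0;

  int pidx(int x, int y) const { return height * (x - 1) + (y - 1); }

  double value(int x, int y) const {
    if (type == 0) {
      const int p = pidx(x, y);
      const double* col = &Mt(0, p);
      const int n = Mt.nrow();
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += col[k] * wd[k];
      return s;
    } else if (type == 1) {
      return v(x - 1, y - 1);
    }
    return vr(x - 1, y - 1) - vp(x - 1, y - 1);
  }

  // OVaRLAP normalized update at afterstate (x, y); exact increment:
  // the value at (x, y) moves by alpha_m * delta.
  void ovarlap_update(int x, int y, double delta) {
    if (delta == 0.0) return;
    const int p = pidx(x, y);
    const double* col = &Mt(0, p);
    const int n = Mt.nrow();
    double nrm = 0.0;
    for (int k = 0; k < n; ++k) nrm += col[k] * col[k];
    if (delta > 0.0) {
      const double c = alpha1 * delta / nrm;
      for (int k = 0; k < n; ++k) {
        w1[k] += c * col[k];
        wd[k] += c * col[k];
      }
    } else {
      const double c = alpha2 * (-delta) / nrm;
      for (int k = 0; k < n; ++k) {
        w2[k] += c * col[k];
        wd[k] -= c * col[k];
      }
    }
  }
};

int softmax_draw(const double q[4], double tau) {
  double m = q[0];
  for (int i = 1; i < 4; ++i) if (q[i] > m) m = q[i];
  double w[4], tot = 0.0;
  for (int i = 0; i < 4; ++i) {
    w[i] = std::exp((q[i] - m) / tau);
    tot += w[i];
  }
  const double u = unif_rand() * tot;
  double acc = 0.0;
  for (int i = 0; i < 3; ++i) {
    acc += w[i];
    if (u < acc) return i;
  }
  return 3;
}

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(LogicalMatrix passable, int start_x, int start_y,
                IntegerMatrix goals, NumericVector goal_rewards,
                double wall_penalty, std::string agent_type, List state,
                List params, double tau, int n_episodes, int max_total_steps,
                int episode_step_cap, bool randomize_start,
                IntegerVector forced_actions, bool record_trace,
                bool log_wall_values) {
  World world;
  world.width = passable.nrow();
  world.height = passable.ncol();
  world.passable = passable;
  world.start_x = start_x;
  world.start_y = start_y;
  world.goals = goals;
  world.goal_rewards = goal_rewards;
  world.wall_penalty = wall_penalty;

  Agent ag;
  ag.height = world.height;
  if (agent_type == "ovarlap") {
    ag.type = 0;
    ag.Mt = as<NumericMatrix>(state["Mt"]);
    ag.w1 = as<std::vector<double>>(state["w1"]);
    ag.w2 = as<std::vector<double>>(state["w2"]);
    ag.wd.resize(ag.w1.size());
    for (size_t k = 0; k < ag.w1.size(); ++k) ag.wd[k] = ag.w1[k] - ag.w2[k];
    ag.alpha1 = as<double>(params["alpha1"]);
    ag.alpha2 = as<double>(params["alpha2"]);
    ag.gamma = as<double>(params["gamma"]);
  } else if (agent_type == "tabular") {
    ag.type = 1;
    ag.v = clone(as<NumericMatrix>(state["v"]));
    ag.alpha_s = as<double>(params["alpha"]);
    ag.gamma_s = as<double>(params["gamma"]);
  } else if (agent_type == "maxpain") {
    ag.type = 2;
    ag.vr = clone(as<NumericMatrix>(state["v_r"]));
    ag.vp = clone(as<NumericMatrix>(state["v_p"]));
    ag.alpha_r = as<double>(params["alpha_r"]);
    ag.alpha_p = as<double>(params["alpha_p"]);
    ag.gamma_r = as<double>(params["gamma_r"]);
    ag.gamma_p = as<double>(params["gamma_p"]);
  } else {
    stop("unknown agent type '%s'", agent_type.c_str());
  }

  std::vector<std::pair<int, int>> free_squares;
  if (randomize_start) {
    for (int x = 1; x <= world.width; ++x)
      for (int y = 1; y <= world.height; ++y)
        if (world.pass(x, y) && world.goal_at(x, y) < 0)
          free_squares.push_back({x, y});
  }

  std::vector<std::pair<int, int>> wall_squares;
  if (log_wall_values) {
    for (int x = 1; x <= world.width; ++x)
      for (int y = 1; y <= world.height; ++y)
        if (!world.pass(x, y)) wall_squares.push_back({x, y});
  }

  std::vector<int> ep_steps, ep_wall_hits, ep_truncated;
  std::vector<double> ep_reward, wall_value_log;

  std::vector<int> tr_ep, tr_x, tr_y, tr_a, tr_tx, tr_ty, tr_nx, tr_ny;
  std::vector<double> tr_r;
  std::vector<int> tr_wall, tr_term;

  const bool forced = forced_actions.size() > 0;
  int forced_i = 0;
  long total_steps = 0;
  bool stop_run = false;

  int episode = 0;
  while (!stop_run && (n_episodes < 0 || episode < n_episodes)) {
    int x, y;
    if (randomize_start) {
      int i = (int)(unif_rand() * (double)free_squares.size());
      if (i >= (int)free_squares.size()) i = (int)free_squares.size() - 1;
      x = free_squares[i].first;
      y = free_squares[i].second;
    } else {
      x = world.start_x;
      y = world.start_y;
    }

    int steps = 0, wall_hits = 0;
    double total_reward = 0.0;
    bool terminal = false, truncated = false;

    // first action of the episode
    int a;
    if (forced) {
      if (forced_i >= forced_actions.size()) break;
      a = forced_actions[forced_i++] - 1;
    } else {
      double q[4];
      for (int i = 0; i < 4; ++i) q[i] = ag.value(x + DX[i], y + DY[i]);
      a = softmax_draw(q, tau);
    }

    while (true) {
      const int tx = x + DX[a], ty = y + DY[a];
      double r;
      int nx, ny;
      bool wall = false;
      const int gi = world.goal_at(tx, ty);
      if (!world.pass(tx, ty)) {
        r = world.wall_penalty;
        nx = x; ny = y;
        wall = true;
        ++wall_hits;
      } else if (gi >= 0) {
        r = world.goal_rewards[gi];
        nx = tx; ny = ty;
        terminal = true;
      } else {
        r = 0.0;
        nx = tx; ny = ty;
      }
      ++steps;
      ++total_steps;
      total_reward += r;

      if (record_trace) {
        tr_ep.push_back(episode + 1);
        tr_x.push_back(x); tr_y.push_back(y);
        tr_a.push_back(a + 1);
        tr_tx.push_back(tx); tr_ty.push_back(ty);
        tr_nx.push_back(nx); tr_ny.push_back(ny);
        tr_r.push_back(r);
        tr_wall.push_back(wall ? 1 : 0);
        tr_term.push_back(terminal ? 1 : 0);
      }

      const double q_cur = ag.value(tx, ty);

      if (terminal) {
        // episodic semantics: no successor action, zero bootstrap
        if (ag.type == 0) {
          ag.ovarlap_update(tx, ty, r - q_cur);
        } else if (ag.type == 1) {
          ag.v(tx - 1, ty - 1) += ag.alpha_s * (r - q_cur);
        } else {
          const double r_plus = r > 0.0 ? r : 0.0;
          const double r_minus = -r > 0.0 ? -r : 0.0;
          ag.vr(tx - 1, ty - 1) +=
              ag.alpha_r * (r_plus - ag.vr(tx - 1, ty - 1));
          ag.vp(tx - 1, ty - 1) +=
              ag.alpha_p * (r_minus - ag.vp(tx - 1, ty - 1));
        }
        x = nx; y = ny;
        if (max_total_steps > 0 && total_steps >= max_total_steps)
          stop_run = true;
        break;
      }

      // non-terminal: draw a' at s' (on-policy SARSA), bootstrap, update
      double q[4];
      for (int i = 0; i < 4; ++i) q[i] = ag.value(nx + DX[i], ny + DY[i]);
      int a2;
      if (forced) {
        if (forced_i >= forced_actions.size()) {
          // injected sequence exhausted: the pending transition gets no
          // update and the run ends
          stop_run = true;
          truncated = true;
          break;
        }
        a2 = forced_actions[forced_i++] - 1;
      } else {
        a2 = softmax_draw(q, tau);
      }

      if (ag.type == 0) {
        const double delta = r + ag.gamma * q[a2] - q_cur;
        ag.ovarlap_update(tx, ty, delta);
      } else if (ag.type == 1) {
        const double delta = r + ag.gamma_s * q[a2] - q_cur;
        ag.v(tx - 1, ty - 1) += ag.alpha_s * delta;
      } else {
        const double boot_r = ag.vr(nx + DX[a2] - 1, ny + DY[a2] - 1);
        // pain channel bootstraps off-policy on the worst next action
        double qmin = q[0];
        for (int i = 1; i < 4; ++i) if (q[i] < qmin) qmin = q[i];
        int mins[4], nmin = 0;
        for (int i = 0; i < 4; ++i) if (q[i] == qmin) mins[nmin++] = i;
        int a_star;
        if (nmin == 1) {
          a_star = mins[0];
        } else {
          int j = (int)(unif_rand() * (double)nmin);
          if (j >= nmin) j = nmin - 1;
          a_star = mins[j];
        }
        const double boot_p = ag.vp(nx + DX[a_star] - 1, ny + DY[a_star] - 1);
        const double r_plus = r > 0.0 ? r : 0.0;
        const double r_minus = -r > 0.0 ? -r : 0.0;
        const double delta_r =
            r_plus + ag.gamma_r * boot_r - ag.vr(tx - 1, ty - 1);
        const double delta_p =
            r_minus + ag.gamma_p * boot_p - ag.vp(tx - 1, ty - 1);
        ag.vr(tx - 1, ty - 1) += ag.alpha_r * delta_r;
        ag.vp(tx - 1, ty - 1) += ag.alpha_p * delta_p;
      }

      x = nx; y = ny;
      a = a2;

      if (max_total_steps > 0 && total_steps >= max_total_steps) {
        stop_run = true;
        truncated = true;
        break;
      }
      if (episode_step_cap > 0 && steps >= episode_step_cap) {
        truncated = true;
        break;
      }
    }

    ep_steps.push_back(steps);
    ep_reward.push_back(total_reward);
    ep_wall_hits.push_back(wall_hits);
    ep_truncated.push_back(truncated ? 1 : 0);
    if (log_wall_values) {
      double s = 0.0;
      for (auto& wsq : wall_squares) s += ag.value(wsq.first, wsq.second);
      wall_value_log.push_back(s / (double)wall_squares.size());
    }
    ++episode;
  }

  List out_state;
  if (ag.type == 0) {
    out_state = List::create(_["w1"] = ag.w1, _["w2"] = ag.w2);
  } else if (ag.type == 1) {
    out_state = List::create(_["v"] = ag.v);
  } else {
    out_state = List::create(_["v_r"] = ag.vr, _["v_p"] = ag.vp);
  }

  std::vector<int> ep_index(ep_steps.size());
  for (size_t i = 0; i < ep_index.size(); ++i) ep_index[i] = (int)(i + 1);

  List out = List::create(
      _["state"] = out_state,
      _["episodes"] = DataFrame::create(
          _["episode"] = ep_index, _["steps"] = ep_steps,
          _["reward"] = ep_reward, _["wall_hits"] = ep_wall_hits,
          _["truncated"] = ep_truncated),
      _["total_steps"] = (double)total_steps);
  if (log_wall_values) out["wall_values"] = wall_value_log;
  if (record_trace) {
    out["trace"] = DataFrame::create(
        _["episode"] = tr_ep, _["x"] = tr_x, _["y"] = tr_y, _["action"] = tr_a,
        _["target_x"] = tr_tx, _["target_y"] = tr_ty, _["reward"] = tr_r,
        _["next_x"] = tr_nx, _["next_y"] = tr_ny, _["wall_hit"] = tr_wall,
        _["terminal"] = tr_term);
  }
  return out;
}
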