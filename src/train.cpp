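// Training inner loop: softmax response choice, schedule state machines and
// tabular TD updates. Mirrors the R-level schedule semantics in
// R/schedules.R (one response = one time step; VI timers advance every step,
// arming is single-capacity and held until collected; tandem components
// complete in order with zero-requirement time-based successors cascading
// within the step). State sequences are pre-generated in R so the sampling
// distribution and RNG order are owned by the R layer.
#include <Rcpp.h>
using namespace Rcpp;

enum Kind { FR = 0, VR = 1, VI = 2, VT = 3 };

struct Comp {
  int kind;
  double value;      // FR ratio only; VR/VI/VT read from seq
  std::vector<double> seq;
  int idx;           // 0-based position in seq
  double progress;
  double elapsed;
  bool armed;
};

struct Arm {
  bool tandem;
  int id;            // 1-based operant response id; 0 = response-independent
  double magnitude;
  std::vector<Comp> comps;
  int compIdx;       // 0-based
};

static double currentSeq(const Comp& c) {
  if (c.idx >= (int)c.seq.size())
    stop("pre-generated schedule sequence exhausted: session end");
  return c.seq[c.idx];
}

// Activation check for a component becoming active without consuming a step:
// VI with an already-elapsed interval arms (but needs a response), VT with an
// elapsed interval completes outright.
static bool activateComp(Comp& c) {
  if (c.kind == VI && c.elapsed >= currentSeq(c)) {
    c.armed = true;
    return false;
  }
  if (c.kind == VT && c.elapsed >= currentSeq(c)) {
    c.idx++;
    c.elapsed = 0;
    return true;
  }
  return false;
}

static void advanceActivation(Arm& a) {
  while (activateComp(a.comps[a.compIdx]) &&
         a.compIdx < (int)a.comps.size() - 1)
    a.compIdx++;
}

static bool stepComp(Comp& c, int response, int armId) {
  switch (c.kind) {
  case FR:
    if (armId > 0 && response == armId) {
      c.progress += 1;
      if (c.progress >= c.value) { c.progress = 0; return true; }
    }
    return false;
  case VR:
    if (armId > 0 && response == armId) {
      c.progress += 1;
      if (c.progress >= currentSeq(c)) { c.progress = 0; c.idx++; return true; }
    }
    return false;
  case VI:
    c.elapsed += 1;
    if (!c.armed && c.elapsed >= currentSeq(c)) c.armed = true;
    if (c.armed && armId > 0 && response == armId) {
      c.armed = false; c.elapsed = 0; c.idx++;
      return true;
    }
    return false;
  case VT:
    c.elapsed += 1;
    if (c.elapsed >= currentSeq(c)) { c.elapsed = 0; c.idx++; return true; }
    return false;
  }
  return false;
}

static bool stepArm(Arm& a, int response) {
  if (!a.tandem) return stepComp(a.comps[0], response, a.id);
  if (!stepComp(a.comps[a.compIdx], response, a.id)) return false;
  for (;;) {
    if (a.compIdx == (int)a.comps.size() - 1) {
      a.compIdx = 0;
      advanceActivation(a);
      return true;
    }
    a.compIdx++;
    if (!activateComp(a.comps[a.compIdx])) return false;
  }
}

static Comp parseComp(const List& x) {
  Comp c;
  std::string k = as<std::string>(x["kind"]);
  c.kind = k == "FR" ? FR : k == "VR" ? VR : k == "VI" ? VI : VT;
  c.value = as<double>(x["value"]);
  if (x.containsElementNamed("seq") && !Rf_isNull(x["seq"])) {
    NumericVector s = x["seq"];
    c.seq.assign(s.begin(), s.end());
  }
  c.idx = as<int>(x["idx"]) - 1;
  c.progress = as<double>(x["progress"]);
  c.elapsed = as<double>(x["elapsed"]);
  c.armed = as<bool>(x["armed"]);
  return c;
}

// [[Rcpp::export(name = ".trainLoopCpp")]]
List trainLoopCpp(NumericMatrix Q, List arms, int nRewards, double alpha,
                  double gamma, double betaC, bool sarsa, double otherMag,
                  double maxSteps, int firstResponse) {
  const int n = Q.ncol();
  std::vector<Arm> A;
  for (int i = 0; i < arms.size(); i++) {
    List ar = arms[i];
    Arm a;
    a.tandem = as<bool>(ar["tandem"]);
    int id = as<int>(ar["id"]);
    a.id = id == NA_INTEGER ? 0 : id;
    a.magnitude = as<double>(ar["magnitude"]);
    a.compIdx = as<int>(ar["compIdx"]) - 1;
    List comps = ar["comps"];
    for (int j = 0; j < comps.size(); j++)
      a.comps.push_back(parseComp(comps[j]));
    A.push_back(a);
  }
  std::vector<bool> isOperant(n + 1, false);
  for (size_t i = 0; i < A.size(); i++)
    if (A[i].id > 0) isOperant[A[i].id] = true;

  std::vector<int> logStep, logPrev, logResp;
  std::vector<double> logRew, logDelta;
  std::vector<int> logDel;

  std::vector<double> w(n);
  int prev = firstResponse;
  int delivered = 0;
  double t = 0;
  // SARSA one-step lag
  int pPrev = 0, pCur = 0;
  double pRew = 0;

  while (delivered < nRewards) {
    t += 1;
    if (t > maxSteps)
      stop("training did not reach the reward criterion within `maxSteps`");
    // softmax choice over row `prev`
    double mx = Q(prev - 1, 0);
    for (int j = 1; j < n; j++) if (Q(prev - 1, j) > mx) mx = Q(prev - 1, j);
    double s = 0;
    for (int j = 0; j < n; j++) {
      w[j] = std::exp(betaC * (Q(prev - 1, j) - mx));
      s += w[j];
    }
    double u = unif_rand() * s;
    int a = n;
    double cum = 0;
    for (int j = 0; j < n; j++) {
      cum += w[j];
      if (u <= cum) { a = j + 1; break; }
    }

    if (sarsa && pPrev > 0) {
      double d = pRew + gamma * Q(pCur - 1, a - 1) - Q(pPrev - 1, pCur - 1);
      Q(pPrev - 1, pCur - 1) += alpha * d;
      logDelta[logDelta.size() - 1] = d;
    }

    double reward = 0;
    bool opDel = false;
    for (size_t i = 0; i < A.size(); i++) {
      if (stepArm(A[i], a)) {
        reward += A[i].magnitude;
        if (A[i].id > 0) { opDel = true; delivered++; }
      }
    }
    if (!isOperant[a]) reward += otherMag;

    double d = NA_REAL;
    if (sarsa) {
      pPrev = prev; pCur = a; pRew = reward;
    } else {
      double mb = Q(a - 1, 0);
      for (int j = 1; j < n; j++) if (Q(a - 1, j) > mb) mb = Q(a - 1, j);
      d = reward + gamma * mb - Q(prev - 1, a - 1);
      Q(prev - 1, a - 1) += alpha * d;
    }

    logStep.push_back((int)t);
    logPrev.push_back(prev);
    logResp.push_back(a);
    logRew.push_back(reward);
    logDelta.push_back(d);
    logDel.push_back(opDel ? 1 : 0);
    prev = a;
  }

  return List::create(
    _["Q"] = Q,
    _["step"] = wrap(logStep),
    _["prev"] = wrap(logPrev),
    _["response"] = wrap(logResp),
    _["reward"] = wrap(logRew),
    _["delta"] = wrap(logDelta),
    _["delivered"] = wrap(logDel),
    _["nSteps"] = (double)t);
}
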