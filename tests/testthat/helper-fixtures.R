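# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# minicore in all the forms the tests need, with sugar uptakes closed
minicore_fixture <- function() {
  if (is.null(.fixture_cache$mk)) {
    mk <- make_minicore_ec()
    ec <- mk$ec
    for (ex in mk$config$substrates$exchange_id) ec <- set_uptake(ec, ex, 0)
    mk$ec_closed <- ec
    sp <- split_model(mk$base)
    b <- sp$model
    for (ex in mk$config$substrates$exchange_id) b <- set_uptake(b, ex, 0)
    mk$base_split_closed <- b
    .fixture_cache$mk <- mk
  }
  .fixture_cache$mk
}

# a 3-reaction chain: SRC (ub 10) -> a -> b -> SINK, maximize SINK
chain_model <- function(src_ub = 10) {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"))
  rxns <- list(
    reaction("SRC", c(a_c = 1), 0, src_ub),
    reaction("CONV", c(a_c = -1, b_c = 1), 0, 1000, gpr = "g1"),
    reaction("SINK", c(b_c = -1), 0, 1000))
  metabolic_model(mets, rxns, objective = "SINK")
}

# two parallel routes a -> b: direct (FAST) and via c (SLOW1 + SLOW2)
parallel_model <- function() {
  mets <- rbind(metabolite("a_c"), metabolite("b_c"), metabolite("c_c"))
  rxns <- list(
    reaction("SRC", c(a_c = 1), 0, 10),
    reaction("FAST", c(a_c = -1, b_c = 1), 0, 1000, gpr = "gf"),
    reaction("SLOW1", c(a_c = -1, c_c = 1), 0, 1000, gpr = "gs1"),
    reaction("SLOW2", c(c_c = -1, b_c = 1), 0, 1000, gpr = "gs2"),
    reaction("SINK", c(b_c = -1), 0, 1000))
  metabolic_model(mets, rxns, objective = "SINK")
}

# batch-solve LPs with scipy's HiGHS backend (independent oracle).
# cases: list of list(obj, Aeq, beq, Ale, ble, lb, ub, maximize)
scipy_lp_batch <- function(cases) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(cases, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
cases = json.load(open(sys.argv[1]))
out = []
for c in cases:
    n = len(c["obj"])
    obj = np.array(c["obj"], float)
    sign = -1.0 if c.get("maximize") else 1.0
    def mat(key):
        m = c.get(key)
        if m is None: return None
        a = np.array(m, float)
        return a.reshape(-1, n)
    Aeq, Ale = mat("Aeq"), mat("Ale")
    beq = c.get("beq"); ble = c.get("ble")
    if beq is not None and not isinstance(beq, list): beq = [beq]
    if ble is not None and not isinstance(ble, list): ble = [ble]
    lb = np.resize(np.array(c.get("lb", 0.0), float), n)
    ub = np.resize(np.array(c.get("ub", np.inf), float), n)
    res = linprog(sign * obj, A_ub=Ale, b_ub=ble, A_eq=Aeq, b_eq=beq,
                  bounds=list(zip(lb, ub)), method="highs")
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(res.status, "other")
    out.append({"status": status,
                "objective": None if res.status else float(sign * res.fun)})
json.dump(out, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("python LP oracle failed")
  jsonlite::read_json(fout, simplifyVector = FALSE)
}
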