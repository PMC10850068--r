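## Shared fixture builders for the test suite. Ground truths are analytic,
## never taken from the code under test.

minimal_entry_yaml <- function(temperature = 310, n_popc = 128,
                               n_sol = 5120, extra = "") {
  paste0(
    "DOI: 10.5281/zenodo.000001\n",
    "TRJ: traj.csv\n",
    "TPR: topol.csv\n",
    "SOFTWARE: synthetic\n",
    if (!is.na(temperature)) paste0("TEMPERATURE: ", temperature, "\n") else "",
    "TRJLENGTH: 500\n",
    "TIMELEFTOUT: 100\n",
    "COMPOSITION:\n",
    "  POPC:\n    NAME: POPC\n    MAPPING: POPC_toy\n    COUNT: ", n_popc, "\n",
    "  SOL:\n    NAME: TIP3\n    MAPPING: SOL_map\n    COUNT: ", n_sol, "\n",
    extra)
}

## experiment entry built in code
make_experiment <- function(kind = "NMR-order-parameters",
                            composition = c(POPC = 100), temperature = 310,
                            waterPerLipid = NULL, counterions = NULL,
                            opData = data.frame(bond = "C2 C2H1",
                                                S_exp = -0.18, dS_exp = 0.02),
                            ffData = data.frame(q = numeric(),
                                                F = numeric(),
                                                dF = numeric())) {
  new("ExperimentEntry", kind = kind,
      conditions = list(composition = composition, temperature = temperature,
                        waterPerLipid = waterPerLipid,
                        counterions = counterions),
      opData = if (kind == "NMR-order-parameters") opData else
        data.frame(bond = character(), S_exp = numeric(), dS_exp = numeric()),
      ffData = ffData)
}

## a tiny FrameEnsemble built by hand
tiny_ensemble <- function(coords, box = c(5, 5, 5), atoms) {
  FrameEnsemble(coords, box = box, atoms = atoms)
}

## rotation matrix from Euler-like angles (used by the alignment oracle)
rot3 <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}
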