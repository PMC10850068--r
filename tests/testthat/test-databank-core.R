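test_that("README.yaml entries parse, round-trip, and validate their schema", {
  entry <- parseSimulationEntry(minimal_entry_yaml())
  expect_s4_class(entry, "SimulationEntry")
  expect_equal(entryTemperature(entry), 310)
  comp <- entryComposition(entry)
  expect_equal(comp$count[comp$molecule == "POPC"], 128L)
  expect_equal(entry@waterPerLipid, 5120 / 128)

  ## parse -> serialize -> parse is identity
  txt <- writeSimulationEntry(entry)
  entry2 <- parseSimulationEntry(txt)
  for (sl in c("rawDataLink", "trajectoryName", "topologyName", "software",
               "temperature", "counterions", "trajectoryLength",
               "equilibrationDiscard", "waterPerLipid"))
    expect_equal(slot(entry2, sl), slot(entry, sl), info = sl)
  expect_equal(entryComposition(entry2), entryComposition(entry))

  ## unknown keys are preserved, not rejected
  entry3 <- parseSimulationEntry(minimal_entry_yaml(
    extra = "CUSTOMKEY: somevalue\n"))
  expect_equal(entry3@extras$CUSTOMKEY, "somevalue")
  expect_match(writeSimulationEntry(entry3), "CUSTOMKEY")
})

test_that("schema and naming errors identify the offending key or molecule", {
  expect_error(parseSimulationEntry(minimal_entry_yaml(temperature = NA)),
               "TEMPERATURE")
  bad <- sub("POPC:\n", "XXPC:\n", minimal_entry_yaml())
  bad <- sub("NAME: POPC", "NAME: XXPC", bad)
  expect_error(parseSimulationEntry(bad), "XXPC")
})

test_that("a directory of entry files yields one parsed entry each", {
  root <- withr::local_tempdir()
  n <- 4
  for (i in seq_len(n)) {
    d <- file.path(root, paste0("sim", i))
    dir.create(d)
    writeLines(minimal_entry_yaml(temperature = 300 + i),
               file.path(d, "README.yaml"))
  }
  entries <- readSimulationEntries(root)
  expect_length(entries, n)
  expect_setequal(vapply(entries, entryTemperature, numeric(1)),
                  300 + seq_len(n))
})

test_that("entry identifiers are deterministic, order- and content-sensitive", {
  trj <- as.raw(c(1, 2, 3, 200, 255))
  top <- as.raw(c(9, 8, 7))
  id1 <- computeEntryId(trj, top)
  expect_identical(id1, computeEntryId(trj, top))
  expect_match(id1, "^[0-9a-f]{32}$")
  trj_flip <- trj; trj_flip[2] <- as.raw(99)
  expect_false(identical(id1, computeEntryId(trj_flip, top)))
  ## swapping trajectory and topology changes the id
  expect_false(identical(id1, computeEntryId(top, trj)))
  expect_error(computeEntryId(raw(0), top), "empty")
})

test_that("atoms resolve through mapping tables to universal names", {
  map <- MappingTable("POPC_fix", data.frame(
    universal_atom = c("M_G1C3_M", "M_G1C3H1_M"),
    ff_atom = c("C2", "H2A"),
    fragment = c("acyl chain sn-1", "acyl chain sn-1")))
  entry <- parseSimulationEntry(minimal_entry_yaml())
  entry@composition$mapping[entry@composition$molecule == "POPC"] <- "POPC_fix"
  res <- resolveAtom(entry, "POPC", "C2", list(POPC_fix = map))
  expect_equal(res$universal_atom, "M_G1C3_M")
  expect_equal(res$fragment, "acyl chain sn-1")
  expect_error(resolveAtom(entry, "POPC", "XX", list(POPC_fix = map)),
               "unmapped-atom")
  ## every atom of the table resolves without error
  for (a in map@rows$ff_atom)
    expect_no_error(resolveAtom(entry, "POPC", a, list(POPC_fix = map)))
})

test_that("mapping tables validate fragments and enumerate C-H bonds", {
  expect_error(MappingTable("bad", data.frame(
    universal_atom = c("C1", "C1"), ff_atom = c("a", "b"),
    fragment = "headgroup")) |> validObject(), "unique")
  bonds <- bondsFromMapping(toyLipidMapping())
  expect_true(all(c("carbon", "hydrogen", "fragment") %in% names(bonds)))
  expect_true(all(paste0(bonds$carbon, "H1") == bonds$hydrogen))
  expect_setequal(unique(bonds$fragment),
                  c("headgroup", "glycerol backbone", "acyl chain sn-1",
                    "acyl chain sn-2"))
})

test_that("experiment matching applies temperature, composition and hydration rules", {
  entry <- parseSimulationEntry(minimal_entry_yaml())   # POPC, 310 K, w/l 40
  e_close <- make_experiment(temperature = 311.5)
  e_far <- make_experiment(temperature = 313.5)
  expect_length(matchExperiments(entry, list(e_close, e_far)), 1)
  expect_identical(matchExperiments(entry, list(e_close, e_far))[[1]]@kind,
                   "NMR-order-parameters")
  ## same system at 313 K vs a 310 K experiment: outside +-2 K
  entry313 <- parseSimulationEntry(minimal_entry_yaml(temperature = 313))
  expect_length(matchExperiments(entry313, list(make_experiment())), 0)
  ## hydration: 30 vs 40 waters per lipid are both fully hydrated
  entry30 <- parseSimulationEntry(minimal_entry_yaml(n_sol = 30 * 128))
  e40 <- make_experiment(waterPerLipid = 40)
  expect_length(matchExperiments(entry30, list(e40)), 1)
  ## low hydration on one side forces the comparison
  entry5 <- parseSimulationEntry(minimal_entry_yaml(n_sol = 5 * 128))
  expect_length(matchExperiments(entry5, list(e40)), 0)
  ## composition within +-3 percentage units
  e_mix <- make_experiment(composition = c(POPC = 98, CHOL = 2))
  e_mix2 <- make_experiment(composition = c(POPC = 90, CHOL = 10))
  expect_length(matchExperiments(entry, list(e_mix, e_mix2)), 1)
})

test_that("widening any matching tolerance never removes a match", {
  entry <- parseSimulationEntry(minimal_entry_yaml())
  exps <- list(make_experiment(temperature = 311.5),
               make_experiment(temperature = 313.5),
               make_experiment(composition = c(POPC = 95, CHOL = 5)),
               make_experiment(waterPerLipid = 10))
  base <- matchExperiments(entry, exps)
  for (ct in c(3, 6, 12)) for (tt in c(2, 4, 8)) {
    wider <- matchExperiments(entry, exps, comp_tol = ct, temp_tol = tt)
    expect_true(all(vapply(base, function(b)
      any(vapply(wider, identical, logical(1), b)), logical(1))),
      info = sprintf("comp_tol=%g temp_tol=%g", ct, tt))
  }
})

test_that("ranking sorts by quality, discards unconverged entries, and is a permutation", {
  reports <- data.frame(
    entry_id = c("a", "b", "c"),
    P_sn1 = c(0.9, 0.5, 0.7), FF_q = c(0.0, 1.2, 0.4),
    tau_rel = c(0.5, 0.8, 0.9))
  rk <- rankSimulations(reports, "P_sn1")
  expect_equal(rk$value, c(0.9, 0.7, 0.5))
  expect_equal(rk$entry_id, c("a", "c", "b"))
  ## permutation of non-discarded input
  expect_setequal(rk$entry_id, reports$entry_id)

  reports$tau_rel[3] <- 2.0
  rk2 <- rankSimulations(reports, "P_sn1")
  expect_false("c" %in% rk2$entry_id)

  rk3 <- rankSimulations(reports[1:2, ], "FF_q")
  expect_equal(rk3$value, c(0.0, 1.2))   # ascending: best form factor first

  expect_error(rankSimulations(reports, "P_everything"), "usage error")

  ## ties break by entry id
  tied <- data.frame(entry_id = c("z", "m", "a"), P_sn1 = 0.5, tau_rel = 0.1)
  expect_equal(rankSimulations(tied, "P_sn1")$entry_id, c("a", "m", "z"))
})

test_that("molecule registry extends and flags membrane components", {
  expect_true("POPC" %in% knownMolecules())
  expect_false("XENO" %in% knownMolecules())
  registerMolecules("XENO")
  expect_true("XENO" %in% knownMolecules())
  expect_true(isMembraneMolecule("POPC"))
  expect_false(isMembraneMolecule("SOL"))
  expect_false(isMembraneMolecule("SOD"))
})
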