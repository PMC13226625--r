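# Workbook parsing, validation and trace output.

test_that("a minimal workbook loads to the expected network", {
  spec <- network_spec(leak_cell(),
                       stimuli = list(stimulus_spec("L", "current_pulse",
                                                    2, 2, 7)))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_network(spec, f)
  sp2 <- load_network(f)
  expect_equal(length(sp2$neurons), 1L)
  expect_equal(length(sp2$neurons[[1]]$compartments[[1]]$channels), 1L)
  expect_equal(length(sp2$stimuli), 1L)
  expect_true(network_equal(spec, sp2))
})

test_that("dangling references are reported with both ends", {
  spec <- network_spec(leak_cell())
  f <- withr::local_tempfile(fileext = ".tsv")
  save_network(spec, f)
  txt <- readLines(f)
  i <- grep("^\\[ChemicalSynapses\\]", txt) + 1L
  txt <- append(txt, "B99\tL\t0.01\t0\t0.01\t0.05\t0\t\t\t\t\t\t\t", after = i)
  writeLines(txt, f)
  expect_error(load_network(f), "B99")
})

test_that("validation names sheet, row and column for bad values", {
  spec <- network_spec(leak_cell())
  f <- withr::local_tempfile(fileext = ".tsv")
  save_network(spec, f)
  txt <- readLines(f)
  txt <- sub("^L\tL\t1\t-60$", "L\tL\tnot_a_number\t-60", txt)
  writeLines(txt, f)
  expect_error(load_network(f), "sheet Neurons.*Cm|Cm.*not numeric")
})

test_that("unknown columns are errors and unknown sheets are warnings", {
  spec <- network_spec(leak_cell())
  f <- withr::local_tempfile(fileext = ".tsv")
  save_network(spec, f)
  txt <- readLines(f)
  writeLines(c(txt, "[Scribbles]", "a\tb", "1\t2"), f)
  expect_warning(load_network(f), "Scribbles")
  txt2 <- sub("^neuron\tcompartment\tCm\tV_init$",
              "neuron\tcompartment\tCm\tV_init\ttypo_col", txt)
  writeLines(txt2, f)
  expect_error(load_network(f), "typo_col")
})

test_that("every fixture round-trips through the workbook identically", {
  for (id in c("leaky", "spiker", "spiker_capool", "gap_pair",
               "plastic_triad", "vdep_pair", "burst_alternator")) {
    fx <- make_fixture(id)
    f <- withr::local_tempfile(fileext = ".tsv")
    save_network(fx$spec, f)
    sp2 <- load_network(f)
    expect_true(network_equal(fx$spec, sp2), label = paste("fixture", id))
    # and save(load(save(x))) is byte-identical (canonical ordering)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    save_network(sp2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("noise round-trips, and an absent noise block stays absent", {
  spec <- network_spec(leak_cell(),
                       noise = noise_spec("L", rate_i = 40, w_i = 2e-5,
                                          tau_i = 0.02, seed = 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_network(spec, f)
  sp2 <- load_network(f)
  expect_true(network_equal(spec, sp2))
  spec0 <- network_spec(leak_cell())
  save_network(spec0, f)
  expect_true(any(grepl("^\\[Noise\\]$", readLines(f))))
  expect_null(load_network(f)$noise)
})

test_that("structural invariants are enforced at construction", {
  expect_error(channel_spec("c", gbar = -1, E = 0), ">= 0")
  expect_error(chemical_synapse("a", "b", 1, 0, tau_rise = 0.05,
                                tau_decay = 0.01), "tau_decay > tau_rise")
  expect_error(chemical_synapse("a", "b", 1, 0, 0.01, 0.05,
                                depression = list(u = 1.5, tau_rec = 1)),
               "u")
  expect_error(electrical_synapse("a", "a", 1), "differ")
  expect_error(
    network_spec(leak_cell(),
                 electrical_synapses = list(electrical_synapse("L", "Z", 1))),
    "Z")
  expect_error(
    network_spec(point_neuron("N", 1, channels = list(
      channel_spec("k", 1, -80,
                   regulation = regulation_link("nope", "inhibition", 1))))),
    "nope")
  # p >= q and q binary
  expect_error(channel_spec("c", 1, 0, activation = gate_spec(0, 5), p = 0L,
                            inactivation = gate_spec(0, -5), q = 1L),
               "p >= q")
})

test_that("workbook parameter addressing patches a single scalar", {
  spec <- make_fixture("leaky")$spec
  sp2 <- set_workbook_param(spec, "Channels:1:gbar", 0.2)
  expect_equal(sp2$neurons[[1]]$compartments[[1]]$channels[[1]]$gbar, 0.2)
  expect_equal(spec$neurons[[1]]$compartments[[1]]$channels[[1]]$gbar, 0.1)
  expect_error(set_workbook_param(spec, "Channels:99:gbar", 1), "row")
  expect_error(set_workbook_param(spec, "Channels:1:nope", 1), "column")
})

test_that("trace output round-trips in both formats", {
  tr <- run_simulation(make_fixture("leaky")$spec,
                       list(duration = 0.1, dt = 1e-3))
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  f_bin <- withr::local_tempfile(fileext = ".rds")
  write_traces(tr, f_tsv, "tsv")
  write_traces(tr, f_bin, "binary")
  df_tsv <- read_traces(f_tsv, "tsv")
  df_bin <- read_traces(f_bin, "binary")
  expect_identical(df_bin, as.data.frame(tr))        # bitwise
  expect_equal(df_tsv$time, tr$time)                 # full precision text
  expect_equal(df_tsv[["L:V"]], trace_series(tr, "L:V"))
  expect_true(all(diff(df_tsv$time) > 0))
  # header: time + one column per series
  expect_identical(names(df_tsv), c("time", names(tr$data)))
  empty <- structure(list(time = numeric(), data = list()),
                     class = "cpg_traces")
  expect_error(write_traces(empty, f_tsv), "empty")
})
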