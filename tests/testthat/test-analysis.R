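# Burst extraction, phase durations, objective and the grid search.

test_that("bursts are maximal runs of close spikes above the size floor", {
  sp <- c(0.1, 0.2, 0.3, 3.0, 3.1, 3.2)
  b <- detect_bursts(sp, max_isi = 1, min_spikes = 2)
  expect_equal(nrow(b), 2)
  expect_equal(b$duration, c(0.2, 0.2), tolerance = 1e-12)
  expect_equal(b$onset, c(0.1, 3.0))
  expect_equal(nrow(detect_bursts(numeric(), 1, 2)), 0)
  expect_equal(nrow(detect_bursts(5, 1, 2)), 0)   # single spike below floor
  expect_equal(detect_bursts(sp, max_isi = 5, min_spikes = 2)$n_spikes, 6L)
})

test_that("phase durations drop the first pattern and summarise the rest", {
  sb <- synthetic_bursts(4, 6, n_patterns = 5, isi = 0.1)
  pro <- detect_bursts(sb$protraction, 0.5, 3)
  ret <- detect_bursts(sb$retraction, 0.5, 3)
  s <- phase_durations(pro, ret)
  expect_false(s$empty)
  expect_equal(s$n, 4)
  expect_equal(s$protraction[["mean"]], 4)
  expect_equal(s$retraction[["mean"]], 6)
  expect_equal(s$protraction[["sd"]], 0)
  # a single pattern is excluded entirely
  sb1 <- synthetic_bursts(4, 6, n_patterns = 1)
  s1 <- phase_durations(detect_bursts(sb1$protraction, 0.5, 3),
                        detect_bursts(sb1$retraction, 0.5, 3))
  expect_true(s1$empty)
})

test_that("jittered durations are recovered within sampling error", {
  sb <- synthetic_bursts(4, 6, n_patterns = 50, isi = 0.05,
                         jitter_sd = 0.1, seed = 13)
  s <- phase_durations(detect_bursts(sb$protraction, 0.5, 3),
                       detect_bursts(sb$retraction, 0.5, 3))
  expect_lt(abs(s$protraction[["mean"]] - 4), 3 * s$protraction[["sem"]] + 1e-9)
  expect_lt(abs(s$retraction[["mean"]] - 6), 3 * s$retraction[["sem"]] + 1e-9)
  # SD recovered within ~3x its own chi^2 sampling error
  se_sd <- 0.1 / sqrt(2 * (s$n - 1))
  expect_lt(abs(s$protraction[["sd"]] - 0.1), 3 * se_sd)
})

test_that("the objective is squared error with an Inf sentinel", {
  sb <- synthetic_bursts(4, 6, n_patterns = 4)
  s <- phase_durations(detect_bursts(sb$protraction, 0.5, 3),
                       detect_bursts(sb$retraction, 0.5, 3))
  expect_equal(phase_objective(s, 4, 6), 0)
  expect_equal(phase_objective(s, 4, 5), 1)
  empty <- phase_durations(detect_bursts(numeric(), 0.5, 3),
                           detect_bursts(numeric(), 0.5, 3))
  expect_identical(phase_objective(empty, 4, 6), Inf)
})

# mock backend: pretends the two swept conductances set the phase
# durations directly, so the objective is (x - a)^2 + (y - b)^2
mock_backend <- function() {
  function(spec) {
    x <- spec$neurons[[1]]$compartments[[1]]$channels[[1]]$gbar
    y <- spec$neurons[[1]]$compartments[[1]]$channels[[2]]$gbar
    structure(list(protraction = c(mean = x, sd = 0, sem = 0),
                   retraction = c(mean = y, sd = 0, sem = 0),
                   n = 3L, empty = FALSE),
              class = "cpg_phase_summary")
  }
}

mock_spec <- function() {
  network_spec(point_neuron("M", 1, channels = list(
    channel_spec("gx", 1, -60), channel_spec("gy", 1, -60))))
}

test_that("grid search recovers a known argmin by exhaustive comparison", {
  mesh <- seq(0.5, 2.5, length.out = 3)  # targets on the mesh
  sw <- grid_search(mock_spec(),
                    param1 = list(address = "Channels:1:gbar", values = mesh),
                    param2 = list(address = "Channels:2:gbar", values = mesh),
                    targets = c(1.5, 2.5), simulate_fn = mock_backend())
  # brute-force oracle over all 9 cells
  obj <- outer(mesh, mesh, function(x, y) (x - 1.5)^2 + (y - 2.5)^2)
  expect_equal(sw$objective, obj)
  expect_equal(sw$argmin$index, c(2, 3))
  expect_equal(sw$argmin$values, c(1.5, 2.5))
  expect_equal(sw$argmin$objective, 0)
  # argmin is invariant under the monotone sqrt transform
  expect_equal(which(sqrt(sw$objective) == min(sqrt(sw$objective))),
               which(sw$objective == min(sw$objective)))
})

test_that("degenerate meshes and ties behave as specified", {
  sw1 <- grid_search(mock_spec(),
                     param1 = list(address = "Channels:1:gbar", values = 2),
                     param2 = list(address = "Channels:2:gbar", values = 3),
                     targets = c(0, 0), simulate_fn = mock_backend())
  expect_equal(sw1$argmin$index, c(1, 1))
  # two equal minima: lowest index pair wins
  sw2 <- grid_search(mock_spec(),
                     param1 = list(address = "Channels:1:gbar",
                                   values = c(1, 3)),
                     param2 = list(address = "Channels:2:gbar",
                                   values = c(5, 5)),
                     targets = c(2, 5), simulate_fn = mock_backend())
  expect_equal(sw2$argmin$index, c(1, 1))
})

test_that("batched execution equals serial execution bitwise", {
  mesh <- seq(0.5, 2.5, length.out = 4)
  args <- list(mock_spec(),
               param1 = list(address = "Channels:1:gbar", values = mesh),
               param2 = list(address = "Channels:2:gbar", values = mesh),
               targets = c(1, 2), simulate_fn = mock_backend())
  s1 <- do.call(grid_search, c(args, batch_size = 1L))
  s4 <- do.call(grid_search, c(args, batch_size = 4L))
  s16 <- do.call(grid_search, c(args, batch_size = 16L))
  expect_identical(s1$objective, s4$objective)
  expect_identical(s1$objective, s16$objective)
})

test_that("a full-size mock sweep carries 3600 cells", {
  mesh1 <- seq(0.5, 1.8, length.out = 60)
  mesh2 <- seq(1.3, 4.0, length.out = 60)
  sw <- grid_search(mock_spec(),
                    param1 = list(address = "Channels:1:gbar", values = mesh1),
                    param2 = list(address = "Channels:2:gbar", values = mesh2),
                    targets = c(1, 2), simulate_fn = mock_backend())
  expect_equal(length(sw$objective), 3600L)
  expect_equal(dim(sw$objective), c(60L, 60L))
  expect_equal(sw$objective[sw$argmin$index[1], sw$argmin$index[2]],
               min(sw$objective))
})

test_that("failing cells leave sentinels and the sweep continues", {
  failing <- function(spec) {
    x <- spec$neurons[[1]]$compartments[[1]]$channels[[1]]$gbar
    if (x > 1.9) stop("numerical blow-up")
    mock_backend()(spec)
  }
  expect_warning(
    sw <- grid_search(mock_spec(),
                      param1 = list(address = "Channels:1:gbar",
                                    values = c(1, 2)),
                      param2 = list(address = "Channels:2:gbar", values = 1),
                      targets = c(1, 1), simulate_fn = failing),
    "failed")
  expect_identical(sw$objective[2, 1], Inf)
  expect_equal(sw$argmin$index, c(1, 1))
})

test_that("sweep results serialise to a manifest plus matrices", {
  mesh <- c(1, 2)
  sw <- grid_search(mock_spec(),
                    param1 = list(address = "Channels:1:gbar", values = mesh),
                    param2 = list(address = "Channels:2:gbar", values = mesh),
                    targets = c(1, 2), simulate_fn = mock_backend())
  d <- withr::local_tempdir()
  save_sweep(sw, d)
  expect_true(file.exists(file.path(d, "sweep.json")))
  man <- jsonlite::read_json(file.path(d, "sweep.json"))
  expect_equal(unlist(man$argmin$index), sw$argmin$index)
  m <- utils::read.delim(file.path(d, "objective.tsv"), check.names = FALSE)
  expect_equal(unname(as.matrix(m[, -1])), unname(sw$objective))
})
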