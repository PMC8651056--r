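test_that("mutant enumeration matches the closed-form counts in deterministic order", {
  singles <- enumerateMutants(c("A", "B", "C"), maxOrder = 1)
  expect_length(singles, 6)
  expect_equal(mutationLabel(singles[[1]]), "A:OFF")
  expect_equal(mutationLabel(singles[[2]]), "A:ON")

  doubles <- enumerateMutants(c("A", "B", "C"), maxOrder = 2, minOrder = 2)
  expect_length(doubles, 12)  # C(3,2) * 2 * 2
  both <- enumerateMutants(c("A", "B", "C"), maxOrder = 2)
  expect_length(both, 18)

  ## closed form |C|*|D| + C(|C|,2)*|D|^2 for all |C| <= 6, |D| in 1:2
  for (nc in 1:6) {
    cand <- paste0("N", seq_len(nc))
    for (dirs in list("OFF", c("OFF", "ON"))) {
      got <- length(enumerateMutants(cand, maxOrder = 2, directions = dirs))
      expect_equal(got, nc * length(dirs) +
                        choose(nc, 2) * length(dirs)^2)
    }
  }
  expect_error(enumerateMutants(character(0)), "non-empty")
  expect_error(enumerateMutants(c("A", "A")), "duplicate")
})

test_that("screens include the wild type, isolate per-mutant errors and stay deterministic", {
  tg <- makeToy("toggle_switch")
  s <- simulationSettings(sampleCount = 400, seed = 21)

  wtOnly <- runScreen(tg, s, list())
  expect_length(screenMutants(wtOnly), 1)
  expect_equal(mutationLabel(screenMutants(wtOnly)[[1]]), "WT")

  screen <- runScreen(tg, s, list(mutationSpec("A", "OFF"),
                                  mutationSpec("Z", "OFF"),
                                  mutationSpec("B", "OFF")))
  expect_equal(sum(is.na(screenErrors(screen))), 3)  # WT + two valid mutants
  expect_match(screenErrors(screen)[3], "unknown node")
  expect_null(screenResults(screen)[[3]])
  ## OFF(A): all mass on the opposite stable state
  lsA <- lastStateDistribution(screenResults(screen)[[2]])
  expect_equal(lsA[["B"]], 1)
  lsB <- lastStateDistribution(screenResults(screen)[[4]])
  expect_equal(lsB[["A"]], 1)

  screen2 <- runScreen(tg, s, list(mutationSpec("A", "OFF"),
                                   mutationSpec("Z", "OFF"),
                                   mutationSpec("B", "OFF")))
  expect_identical(lapply(screenResults(screen), function(r)
    if (is.null(r)) NULL else lastStateDistribution(r)),
    lapply(screenResults(screen2), function(r)
      if (is.null(r)) NULL else lastStateDistribution(r)))
})

test_that("phenotype filtering thresholds, sorting and constraint checks behave", {
  tg <- makeToy("toggle_switch")
  s <- simulationSettings(sampleCount = 500, seed = 31)
  screen <- runScreen(tg, s, enumerateMutants(c("A", "B"), maxOrder = 1))

  all <- filterPhenotype(screen, phenotypeQuery(c(A = 1), threshold = 0))
  expect_true(all(diff(all$statistic) <= 0))            # sorted descending
  expect_true("A:ON" %in% all$mutant)

  locked <- filterPhenotype(screen, phenotypeQuery(c(A = 1, B = 0), threshold = 0.999))
  ## only clamp-locked mutants reach probability 1
  expect_setequal(locked$mutant, c("A:ON", "B:OFF"))

  ## strict inequality at the boundary
  exact1 <- filterPhenotype(screen, phenotypeQuery(c(A = 1, B = 0), threshold = 1))
  expect_equal(nrow(exact1), 0)

  expect_error(
    filterPhenotype(screen, phenotypeQuery(c(Q = 1), 0.1)),
    "non-output")
})

test_that("complementary phenotype queries partition each mutant's last-state mass", {
  nk <- makeNKNetwork(5, 2, seed = 14)
  s <- simulationSettings(sampleCount = 300, seed = 41)
  screen <- runScreen(nk, s, enumerateMutants(nodeNames(nk)[1:2], maxOrder = 1))
  for (i in seq_along(screenResults(screen))) {
    r <- screenResults(screen)[[i]]
    on <- phenotypeStatistic(r, phenotypeQuery(c(N3 = 1)))
    off <- phenotypeStatistic(r, phenotypeQuery(c(N3 = 0)))
    expect_equal(on + off, 1, tolerance = 1e-12)
  }
})

test_that("screen export writes per-mutant directories and a summary table", {
  tg <- makeToy("toggle_switch")
  screen <- runScreen(tg, simulationSettings(sampleCount = 100, seed = 3),
                      enumerateMutants("A", maxOrder = 1))
  dir <- tempfile("screen")
  summary <- writeScreenFiles(screen, dir)
  expect_equal(summary$mutant, c("WT", "A:OFF", "A:ON"))
  expect_true(file.exists(file.path(dir, "screen_summary.tsv")))
  expect_true(file.exists(file.path(dir, "WT", "result_last_state.tsv")))
})
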