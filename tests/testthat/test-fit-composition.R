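test_that("monomer parameters are recovered from pure monomer spots", {
  spec <- mixture_spec(data.frame(n_subunits = 1L, fraction = 1),
                       paper_model(), 10000, seed = 11)
  tab <- simulate_spot_table(spec)
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- fit_monomer_dimer(h, nu = 0.3, low_region = c(0, max(tab$intensity)))
  expect_lt(abs(fit$model$mu / log(500) - 1), 0.02)
  expect_lt(abs(fit$model$sigma / 0.35 - 1), 0.05)
  expect_lt(fit$weights["dimer"], 0.05)
})

test_that("monomer:dimer weight ratio is recovered from a 2:1 mixture", {
  spec <- mixture_spec(data.frame(n_subunits = c(1L, 2L),
                                  fraction = c(2 / 3, 1 / 3)),
                       paper_model(), 20000, seed = 12)
  tab <- simulate_spot_table(spec)
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- fit_monomer_dimer(h, nu = 0.3, low_region = c(0, max(tab$intensity)))
  truth <- detected_weights(spec)
  expect_lt(abs(fit$weights["monomer"] - truth[1]), 0.1)
  expect_lt(abs(fit$weights["dimer"] - truth[2]), 0.1)
})

test_that("an empty fit region is rejected", {
  h <- intensity_histogram(seq(0, 1000, by = 10), rep(0:1, length.out = 100))
  expect_error(fit_monomer_dimer(h, low_region = c(900, 1000)),
               "non-empty bins")
})

test_that("dark-fraction estimation recovers the truth and is monotone", {
  model <- paper_model()
  run_nu <- function(nu_true, seed) {
    comp <- data.frame(n_subunits = c(1L, 2L, 12L), fraction = c(0.3, 0.1, 0.6))
    m <- monomer_model(log(500), 0.35, nu_true)
    tab <- simulate_spot_table(mixture_spec(comp, m, 20000, seed = seed))
    h <- build_histogram(tab$intensity[tab$detected])
    low <- fit_monomer_dimer(h, nu = nu_true)
    as.numeric(estimate_dark_fraction(h, low$model))
  }
  expect_lt(abs(run_nu(0.3, 41) - 0.3), 0.05)
  # no-dark limit
  expect_lt(run_nu(0, 42), 0.05)
  # higher dark fraction shifts the dodecamer peak down: estimates order
  expect_gt(run_nu(0.4, 43), run_nu(0.1, 43))
})

test_that("dark-fraction estimation demands a high-intensity peak", {
  spec <- mixture_spec(data.frame(n_subunits = 1L, fraction = 1),
                       paper_model(), 5000, seed = 14)
  tab <- simulate_spot_table(spec)
  h <- build_histogram(tab$intensity[tab$detected])
  expect_error(estimate_dark_fraction(h, paper_model()),
               "no dodecamer population")
})

test_that("dark-fraction recovery error shrinks with sample size", {
  # median absolute error over seeds must decrease as n grows 10x
  err_at <- function(n) {
    errs <- vapply(1:6, function(s) {
      tab <- simulate_spot_table(holoenzyme_scenario(n_spots = n, seed = s))
      h <- build_histogram(tab$intensity[tab$detected])
      low <- fit_monomer_dimer(h, nu = 0.3)
      abs(as.numeric(estimate_dark_fraction(h, low$model)) - 0.3)
    }, numeric(1))
    median(errs)
  }
  e3 <- err_at(1000); e4 <- err_at(10000)
  expect_lte(e4, e3 + 1e-9)
})

test_that("three-component weights are recovered from a clean mixture", {
  spec <- three_comp_mixture(seed = 3)
  tab <- simulate_spot_table(spec)
  rep <- fit_oligomer_composition(tab$intensity[tab$detected])
  truth <- detected_weights(spec)
  expect_lt(max(abs(rep$mixture_fit$weights - truth)), 0.03)
  expect_lt(abs(rep$model$mu / log(500) - 1), 0.02)
  expect_lt(abs(rep$model$sigma / 0.35 - 1), 0.05)
})

test_that("pure dodecamer input yields near-zero monomer and dimer weights", {
  m <- paper_model()
  tab <- simulate_spot_table(
    mixture_spec(data.frame(n_subunits = 12L, fraction = 1), m, 10000,
                 seed = 15))
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- suppressWarnings(three_component_fit(h, m))
  expect_lt(fit$weights["n1"] + fit$weights["n2"], 0.02)
  expect_gt(fit$weights["n12"], 0.95)
})

test_that("hexamer contamination appears as positive mid-band residual", {
  m <- paper_model()
  comp <- data.frame(n_subunits = c(1L, 2L, 6L, 12L),
                     fraction = c(0.25, 0.1, 0.10, 0.55))
  tab <- simulate_spot_table(mixture_spec(comp, m, 20000, seed = 16))
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- suppressWarnings(three_component_fit(h, m))
  x <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  wbin <- diff(h$bin_edges)
  d2q99 <- pmf_quantile(n_mer_distribution(m, 2, detected = TRUE), 0.99)
  d12 <- n_mer_distribution(m, 12, detected = TRUE)
  mode12 <- pmf_grid(d12)[which.max(d12$masses)]
  mid <- x > d2q99 & x < mode12
  pos_res <- pmax(fit$residual, 0) * wbin
  # positive residual mass concentrates between the dimer and dodecamer peaks
  expect_gt(sum(pos_res[mid]), 0.6 * sum(pos_res))
  expect_gt(sum(pos_res[mid]), 0.03)
  expect_length(fit$residual, length(h$counts))
})

test_that("species percentages sum to 100 and track a 30/0/70 mixture", {
  spec <- three_comp_mixture(seed = 5)
  tab <- simulate_spot_table(spec)
  rep <- fit_oligomer_composition(tab$intensity[tab$detected])
  truth <- detected_weights(spec)
  p <- rep$percentages
  expect_equal(sum(p), 100, tolerance = 0.5)
  expect_lt(abs(p["smaller"] - 100 * (truth[1] + truth[2])), 3)
  expect_lt(abs(p["dodecamer"] - 100 * truth[3]), 3)
  expect_lt(p["intermediate"], 3)
  expect_lt(p["aggregate"], 3)
})

test_that("all-monomer input is classified entirely as smaller species", {
  m <- paper_model()
  tab <- simulate_spot_table(
    mixture_spec(data.frame(n_subunits = 1L, fraction = 1), m, 8000,
                 seed = 17))
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- suppressWarnings(three_component_fit(h, m))
  p <- species_percentages(fit)$percentages
  expect_gt(p["smaller"], 97)
})

test_that("user-supplied overlapping species boundaries are rejected", {
  spec <- three_comp_mixture(seed = 6)
  tab <- simulate_spot_table(spec)
  h <- build_histogram(tab$intensity[tab$detected])
  fit <- suppressWarnings(three_component_fit(h, paper_model()))
  expect_error(
    species_percentages(fit, boundaries = list(
      dimer_upper = 2000, dodecamer_band = c(1500, 8000),
      aggregate_lower = 9000)),
    "overlap")
})

test_that("activation doubles the smaller-species signal in a paired design", {
  run <- function(sf) {
    tab <- simulate_spot_table(
      holoenzyme_scenario(seed = 33, smaller_fraction = sf))
    fit_oligomer_composition(tab$intensity[tab$detected])$percentages["smaller"]
  }
  unact <- run(0.05); act <- run(0.10)
  ratio <- act / unact
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 2.7)
})

test_that("composition reports serialize to JSON with residual CSV", {
  spec <- three_comp_mixture(n_spots = 8000, seed = 7)
  tab <- simulate_spot_table(spec)
  rep <- fit_oligomer_composition(tab$intensity[tab$detected], nu = 0.3,
                                  seed = 7)
  path <- file.path(tempdir(), "report.json")
  write_fit_report(rep, path)
  out <- jsonlite::read_json(path)
  expect_equal(out$model$nu, 0.3)
  expect_equal(out$seed, 7)
  res <- read.csv(sub("\\.json$", "_residual.csv", path))
  expect_equal(nrow(res), length(rep$hist$counts))
})
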