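test_that("simulated matches hit exactly 240 s of combat with alternating structure", {
  cfg <- sim_config(seed = 1)
  for (s in c(2, 17, 400)) {
    for (scen in scenario_levels()) {
      m <- simulate_match(cfg, scen, seed = s)
      seg <- m$segments
      combat <- sum(seg$duration[seg$kind != "pause"])
      expect_equal(combat, 240, tolerance = 1e-9)
      expect_true(all(seg$duration >= 0))
      # starts standing, ends on combat, pause count = blocks - 1
      expect_equal(seg$kind[1], "standing")
      expect_true(seg$kind[nrow(seg)] != "pause")
      n_blocks <- sum(seg$kind == "standing")
      expect_equal(sum(seg$kind == "pause"), n_blocks - 1)
      # groundwork only ever directly follows standing
      gw <- which(seg$kind == "groundwork")
      if (length(gw)) expect_true(all(seg$kind[gw - 1] == "standing"))
    }
  }
})

test_that("attack onsets lie within combat segments on the wall clock", {
  cfg <- sim_config(seed = 1)
  for (s in 1:5) {
    m <- simulate_match(cfg, "CON", seed = s)
    seg <- m$segments
    combat_rows <- seg$kind != "pause"
    for (w in m$attacks$onset_wall) {
      inside <- any(combat_rows & seg$start_wall <= w + 1e-9 &
                      w <= seg$start_wall + seg$duration + 1e-9)
      expect_true(inside)
    }
    expect_true(all(m$attacks$outcome %in% c("none", "wazari", "ippon")))
  }
})

test_that("zero attack rate gives an attack-free match", {
  cfg <- sim_config(seed = 3)
  cfg$scenario_effects$CON$attack_rate <- 0
  m <- simulate_match(cfg, "CON", seed = 3)
  expect_equal(nrow(m$attacks), 0)
  expect_true(is.na(effectiveness(0, 0, 0)))  # undefined downstream
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_athletes = 3), ">= 4")
  expect_error(sim_config(match_duration = 0), "positive")
  cfg <- sim_config()
  cfg$scenario_effects$CON$pause_mean <- -1
  expect_error(simulate_match(cfg, "CON", seed = 1), "positive")
  expect_error(simulate_match(sim_config(), "BOGUS", seed = 1), "scenario")
})

test_that("physiological series are sampled at the eight fixed timepoints", {
  cfg <- sim_config(seed = 5)
  ph <- simulate_physio(cfg, scenario = "CON", seed = 5)
  for (v in ph) {
    expect_equal(names(v$values),
                 c("rest", "pre", "post", "rec2", "rec4", "rec6",
                   "rec8", "rec10"))
    expect_true(all(v$values > 0))
  }
  # RPE stays on the 6-20 integer scale
  rpe <- ph$rpe$values
  expect_true(all(rpe == round(rpe)))
  expect_true(all(rpe >= 6 & rpe <= 20))
})

test_that("noise-free response magnitude appears exactly in post minus pre", {
  cfg <- sim_config(seed = 5, noise_sd = 0)
  cfg$scenario_effects$CON$lactate$response <- 6.25
  ph <- simulate_physio(cfg, scenario = "CON",
                        athlete_factors = c(0, 0, 0), seed = 5)
  v <- ph$lactate$values
  expect_equal(v[["post"]] - v[["pre"]], 6.25)
})

test_that("recovery is monotone after the peak; zero decay constant gives zero decay", {
  cfg <- sim_config(seed = 8)
  for (s in 1:10) {
    ph <- simulate_physio(cfg, scenario = "IMPA15", seed = s)
    for (v in ph) {
      ps <- physio_summary(v)
      path <- v$values[c("post", "rec2", "rec4", "rec6", "rec8", "rec10")]
      i_pk <- which.max(path)
      expect_true(all(diff(path[i_pk:length(path)]) <= 1e-9))
      expect_true(ps$peak >= ps$post)
      expect_true(ps$time_to_peak %in% c(0, 2, 4, 6, 8, 10))
    }
  }
  cfg0 <- sim_config(seed = 8, noise_sd = 0)
  cfg0$scenario_effects$CON$heart_rate$k <- 0
  ph <- simulate_physio(cfg0, scenario = "CON", seed = 8)
  expect_equal(physio_summary(ph$heart_rate)$rate_of_decay, 0)
})

test_that("cohorts are reproducible and share the once-measured columns", {
  cfg <- sim_config(n_athletes = 6, seed = 42)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(sim_config(n_athletes = 6, seed = 43))
  expect_false(identical(d1$CON, d3$CON))
  shared <- default_catalog()$code[default_catalog()$shared]
  for (code in shared) {
    expect_identical(d1$CON[[code]], d1$IMPA15[[code]])
    expect_identical(d1$CON[[code]], d1$IMPA40[[code]])
  }
  expect_true(all(vapply(d1, function(d)
    all(is.finite(as.matrix(d[, default_catalog()$code])) |
          is.na(as.matrix(d[, default_catalog()$code]))), logical(1))))
})

test_that("derived-metric identities hold on every generated dataset", {
  ds <- simulate_cohort(sim_config(seed = 99))
  for (d in ds) {
    expect_equal(d$TSCT + d$TGCT, rep(240, nrow(d)), tolerance = 1e-9)
    expect_equal(d$CF * d$ACT, d$TSCT + d$TGCT, tolerance = 1e-9)
    expect_equal(d$APT, d$TPT / (d$CF - 1), tolerance = 1e-9)
    expect_equal(d[["E:P"]], d$ACT / d$APT, tolerance = 1e-9)
    expect_equal(d$EFFIC, 10 * d$IP + 7 * d$WA)
    ok <- d$Att > 0
    expect_equal(d$EFFEC[ok], 100 * (d$IP[ok] + d$WA[ok]) / d$Att[ok])
    expect_equal(d$DLac, d$POSTLac - d$PRELac, tolerance = 1e-9)
    expect_equal(d$DHR, d$POSTHR - d$PREHR, tolerance = 1e-9)
    expect_equal(d$DRPE, d$POSTRPE - d$PRERPE, tolerance = 1e-9)
    expect_true(all(d$LacPEAK >= d$POSTLac))
    expect_true(all(d$TRPLac %in% c(0, 2, 4, 6, 8, 10)))
  }
})

test_that("two parameters with unit loading on one factor correlate perfectly when noise-free", {
  cfg <- sim_config(n_athletes = 8, seed = 13, noise_sd = 0)
  sp <- cfg$shared_params
  sp[sp$code == "HT", c("l_size", "l_anaerobic", "l_skill")] <- c(1, 0, 0)
  sp[sp$code == "WS", c("l_size", "l_anaerobic", "l_skill")] <- c(1, 0, 0)
  cfg$shared_params <- sp
  ds <- simulate_cohort(cfg)
  for (d in ds) expect_equal(spearman_rho(d$HT, d$WS), 1)
})

test_that("the planted body-size pair shows a strong sample correlation", {
  rhos <- vapply(1:30, function(s) {
    d <- simulate_cohort(sim_config(seed = 1000 + s))$CON
    spearman_rho(d$BM, d$THC)
  }, numeric(1))
  expect_gt(median(rhos), 0.7)
})

test_that("scenario CSVs round-trip through disk with the sidecar", {
  dir <- withr::local_tempdir()
  ds <- simulate_cohort(sim_config(n_athletes = 5, seed = 2))
  write_scenario_csvs(ds, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_scenario_csvs(dir)
  for (s in scenario_levels()) {
    expect_equal(names(back[[s]]), names(ds[[s]]))
    expect_equal(as.matrix(back[[s]][, -1]), as.matrix(ds[[s]][, -1]),
                 tolerance = 1e-12)
  }
  side <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(side$seed, 2)
  expect_equal(side$n_athletes, 5)
})
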