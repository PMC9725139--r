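test_that("generate_pwm_sites is deterministic and honors its model", {
  g0 <- generate_pwm_sites("ACGTACGT", n = 6, mutation_prob = 0, seed = 1)
  expect_true(all(g0$sites == "ACGTACGT"))
  g1 <- generate_pwm_sites("ACGTACGT", n = 30, mutation_prob = 0.2, seed = 5)
  g2 <- generate_pwm_sites("ACGTACGT", n = 30, mutation_prob = 0.2, seed = 5)
  expect_identical(g1$sites, g2$sites)
  expect_false(identical(
    g1$sites,
    generate_pwm_sites("ACGTACGT", 30, 0.2, seed = 6)$sites))
  expect_error(generate_pwm_sites("ACGU", 5, 0.1, 1), "ACGT")
  expect_error(generate_pwm_sites("ACGT", 5, 0.8, 1), "0.75")
})

test_that("empirical mismatch frequency matches mutation_prob (3-sigma)", {
  n <- 1e4; p <- 0.15
  g <- generate_pwm_sites("ACGTACGTAC", n = n, mutation_prob = p, seed = 11)
  mat <- do.call(rbind, strsplit(g$sites, ""))
  cons <- strsplit("ACGTACGTAC", "")[[1]]
  mism <- colMeans(sweep(mat, 2, cons, "!="))
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(mism - p) < 3.5 * sigma))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(runif(0))
  invisible(generate_pwm_sites("ACGT", 10, 0.3, seed = 2))
  invisible(generate_peak_table(20, seed = 3))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("peak-table generator places the spike as requested", {
  tab <- generate_peak_table(50, spike_quantile = 1.0, seed = 2)
  expect_equal(tab$snr[tab$role == "positive"], max(tab$snr))
  expect_identical(generate_peak_table(50, seed = 7),
                   generate_peak_table(50, seed = 7))
  expect_error(generate_peak_table(2), ">= 3")
})

test_that("param grids respect ranges, pins and LHS uniqueness", {
  g <- generate_param_grid(list(f = c(1, 100), Cp = c(0.1, 100)),
                           n = 200, method = "lhs", seed = 3)
  expect_true(all(g$f >= 1 & g$f <= 100))
  expect_true(all(g$Cp >= 0.1 & g$Cp <= 100))
  expect_equal(nrow(unique(g)), 200)
  pin <- generate_param_grid(list(f = 5, D = c(1, 10)), n = 4,
                             method = "grid")
  expect_true(all(pin$f == 5))
  expect_equal(nrow(generate_param_grid(list(f = 2), n = 3,
                                        method = "grid")), 1)
  expect_error(generate_param_grid(list(f = c(10, 1)), 5), "inverted")
  expect_identical(generate_param_grid(list(f = c(1, 9)), 20, seed = 4),
                   generate_param_grid(list(f = c(1, 9)), 20, seed = 4))
})

test_that("FASTA round-trip preserves sites and autoregulation flags", {
  g <- generate_pwm_sites("TTGACAATTTCAGG", 8, 0.2, seed = 21)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_sites_fasta(g$sites, fa, autoregulated = c(TRUE, rep(FALSE, 7)))
  back <- read_sites_fasta(fa)
  expect_identical(back$sequence, unname(g$sites))
  expect_identical(back$site_id, names(g$sites))
  expect_identical(back$autoregulated, c(TRUE, rep(FALSE, 7)))
  # byte-identical output under the same seed
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_sites_fasta(generate_pwm_sites("TTGACAATTTCAGG", 8, 0.2, 21)$sites,
                    fa2, autoregulated = c(TRUE, rep(FALSE, 7)))
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("TSV round-trip keeps the dialect", {
  df <- data.frame(tf = c("a b", "c"), snr = c(1.5, 2.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(df, path)
  expect_identical(read_tsv(path), df)
  expect_false(any(grepl('"', readLines(path))))
})

test_that("config files build parameter sets, with override precedence", {
  cfg <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(f = 5, Rb = 2.5, D = 4, K = 0.5, Cp = 60,
                            Ct = 3, normalized = TRUE),
                       cfg, auto_unbox = TRUE)
  got <- read_config(cfg)
  expect_s3_class(got$params, "tcs_params")
  expect_equal(got$params$Cp, 60)
  over <- read_config(cfg, overrides = list(Cp = 10))
  expect_equal(over$params$Cp, 10)
  # dimensional config goes through normalization
  cfg2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("f: 5", "Cp: 4", "Ct: 0.8", "Rb: 0.25", "K_auto: 0.1"), cfg2)
  p2 <- read_config(cfg2)$params
  expect_equal(p2$Cp, 40)
  expect_equal(p2$Ct, 8)
  # full-model rates subsection
  cfg3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(f = 2, Rb = 1, normalized = TRUE,
                            full_rates = list(k_k = 3)),
                       cfg3, auto_unbox = TRUE)
  expect_equal(read_config(cfg3)$rates$k_k, 3)
})

test_that("CLI subcommands run end to end and write sidecars", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(f = 5, Rb = 2.5, D = 4, K = 0.5, Cp = 60,
                            Ct = 3, normalized = TRUE),
                       cfg, auto_unbox = TRUE)
  out <- file.path(dir, "profile.tsv")
  suppressMessages(
    tcs_cli(c("lg-profile", "--config", cfg, "--out", out,
              "--rt-grid", "0.1,100,50")))
  prof <- read_tsv(out)
  expect_equal(nrow(prof), 50)
  expect_true(all(c("LG_A", "LG_B", "LG_F", "LG3") %in% names(prof)))
  meta <- jsonlite::fromJSON(paste0(out, ".meta.json"))
  expect_equal(meta$params$f, 5)
  expect_gt(meta$max_LG3, 1)
  out2 <- file.path(dir, "ss.tsv")
  suppressMessages(tcs_cli(c("steady-states", "--config", cfg,
                             "--out", out2)))
  expect_equal(nrow(read_tsv(out2)), 3)
  out3 <- file.path(dir, "decoys.tsv")
  suppressMessages(tcs_cli(c("decoys", "--relative-signal", "0.62",
                             "--base-copy-number", "96", "--out", out3)))
  expect_equal(read_tsv(out3)$copy_number, 60)
  expect_error(tcs_cli(character(0)), "usage")
  expect_error(suppressMessages(tcs_cli(c("lg-profile"))), "--config")
})
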