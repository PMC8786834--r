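test_that("cell tables honour the configured probabilities and seed contract", {
  cfg <- effect_config()
  for (mk in names(cfg$groups$GP3$markers)) {
    cfg$groups$GP3$markers[[mk]]$epithelial <- 0
    cfg$groups$GP3$markers[[mk]]$stromal <- 0
  }
  tab <- generate_cell_table(cfg, "GP3", n_cells = 300, seed = 1)
  for (mk in c("MCT1", "MCT4", "HIF1A_nuclear"))
    expect_true(all(tab[[mk]] == "negative"))

  cfg2 <- effect_config()
  t1 <- generate_cell_table(cfg2, "GP5", seed = 7)
  t2 <- generate_cell_table(cfg2, "GP5", seed = 7)
  expect_identical(t1, t2)
  expect_false(identical(t1, generate_cell_table(cfg2, "GP5", seed = 8)))

  expect_error(generate_cell_table(cfg2, "GP9"), "invalid group")
  expect_gte(sum(t1$compartment == "epithelial"), 1)
  expect_gte(sum(t1$compartment == "stromal"), 1)
})

test_that("default GP5 glands express more epithelial LDHA than GP3 glands", {
  cfg <- effect_config()
  hits <- vapply(seq_len(100), function(s) {
    g3 <- generate_cell_table(cfg, "GP3", n_cells = 500, seed = 2000 + s)
    g5 <- generate_cell_table(cfg, "GP5", n_cells = 500, seed = 4000 + s)
    mean(g5$LDHA[g5$compartment == "epithelial"]) >
      mean(g3$LDHA[g3$compartment == "epithelial"])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("expression tables: reproducibility and null type-I calibration", {
  cfg <- effect_config()
  e1 <- generate_expression_table(cfg, seed = 5)
  e2 <- generate_expression_table(cfg, seed = 5)
  expect_identical(e1, e2)
  expect_equal(as.vector(table(e1$primary_gp)), c(197L, 250L, 50L))
  expect_error(generate_expression_table(cfg, group_sizes = c(GP3 = 1, GP4 = 5)),
               ">= 2")

  # zero shifts: two-sided Mann-Whitney p is uniform, rejection near 0.05
  null_cfg <- effect_config()
  for (g in names(null_cfg$expression$shifts))
    null_cfg$expression$shifts[[g]][] <- 0
  rej <- vapply(seq_len(500), function(s) {
    ex <- generate_expression_table(null_cfg, group_sizes = c(GP3 = 60, GP4 = 60),
                                    seed = 10000 + s)
    v <- transform_rsem(ex$LDHA)
    mann_whitney(v[ex$primary_gp == "GP3"], v[ex$primary_gp == "GP4"],
                 mode = "normal")$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("default expression shifts are detected at cohort-scale group sizes", {
  cfg <- effect_config()
  ok <- vapply(seq_len(100), function(s) {
    ex <- generate_expression_table(cfg, group_sizes = c(GP3 = 197, GP4 = 250),
                                    seed = 20000 + s)
    p_of <- function(gene) {
      v <- transform_rsem(ex[[gene]])
      mann_whitney(v[ex$primary_gp == "GP3"], v[ex$primary_gp == "GP4"],
                   mode = "normal")$p
    }
    p_of("SLC16A3") < 0.05 && p_of("LDHA") < 0.05 && p_of("LDHB") < 0.05 &&
      p_of("SLC16A1") >= 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.90)
})

test_that("cohort generation reproduces the supplied %GP4 values and seed", {
  syn <- generate_cohort(effect_config(), n_lesions = 13, seed = 3,
                         imaging = FALSE)
  gp4 <- gp4_numeric(hp13c:::reference_gp4_values())
  expect_equal(syn$cohort$pctGP4, gp4$value)
  expect_equal(syn$cohort$pctGP4_censored, gp4$censored)
  expect_equal(nrow(syn$cohort), 13)

  syn2 <- generate_cohort(effect_config(), n_lesions = 13, seed = 3,
                          imaging = FALSE)
  expect_identical(syn$cohort, syn2$cohort)

  expect_error(generate_cohort(effect_config(), n_lesions = 1), "n_lesions")
  expect_error(generate_cohort(effect_config(), n_lesions = 4,
                               gp4_distribution = c(5, 5, 5, 5),
                               imaging = FALSE),
               "degenerate")
  # all downstream metrics are present with no missing fields
  expect_false(anyNA(syn$cohort[, c("lactateSNR", "pyruvateSNR",
                                    "n_epithelial", "combined_LDH_epi_total",
                                    "MCT4_epi_stroma_ratio")]))
})

test_that("the correlation knob governs realized metric rank-correlation", {
  # decoupled: at 100 lesions the null sd of rs is ~0.1, so |rs| < 0.2 in
  # ~95% of draws
  rs0 <- vapply(seq_len(40), function(s) {
    co <- generate_cohort(effect_config(), 100, corr = 0, seed = 500 + s,
                          imaging = FALSE)$cohort
    spearman_cor(co$lactateSNR, co$combined_LDH_epi_total)$rs
  }, 0)
  expect_gte(mean(abs(rs0) < 0.2), 0.80)

  # strongly coupled at the study size
  rs9 <- vapply(seq_len(40), function(s) {
    co <- generate_cohort(effect_config(), 13, corr = 0.9, seed = 700 + s,
                          imaging = FALSE)$cohort
    spearman_cor(co$lactateSNR, co$combined_LDH_epi_total)$rs
  }, 0)
  expect_gte(stats::median(rs9), 0.6)
})

test_that("full-imaging cohort lands in the printed kPL window", {
  syn <- generate_cohort(effect_config(), n_lesions = 13, corr = 0.9, seed = 1)
  co <- syn$cohort
  expect_length(syn$phantoms, 13)
  expect_true(all(co$kpl_true >= 0.003 & co$kpl_true <= 0.018))
  expect_gte(mean(co$meanKPL), 0.003)
  expect_lte(mean(co$meanKPL), 0.018)
  # the measured rates preserve the ground-truth ordering
  expect_gte(spearman_cor(co$meanKPL, co$kpl_true)$rs, 0.7)
})
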