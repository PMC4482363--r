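test_that("variant affinity table matches the receptor-complex biology", {
  expect_identical(variant_affinities("none")[c("myd88", "pi3k")],
                   list(myd88 = "Low", pi3k = "Low"))
  expect_identical(variant_affinities("wt")[c("myd88", "pi3k")],
                   list(myd88 = "High", pi3k = "High"))
  expect_identical(variant_affinities("d448")[c("myd88", "pi3k")],
                   list(myd88 = "Low", pi3k = "High"))
  expect_identical(variant_affinities("r425")[c("myd88", "pi3k")],
                   list(myd88 = "High", pi3k = "Low"))
})

test_that("rule tables wire the cascade in sequence", {
  cfg <- default_config()
  rules <- cascade_rules(cfg)
  chain <- rules[match(c("myd88_activates_irak", "irak_activates_traf",
                         "traf_activates_tak", "tak_activates_ikk"),
                       rules$name), ]
  expect_identical(chain$type_a, c("MYD88", "IRAK", "TRAF", "TAK"))
  expect_identical(chain$type_b, c("IRAK", "TRAF", "TAK", "IKK"))
  # variant scales only its own adapter radius
  r_wt <- cascade_rules(cfg)
  cfg_d <- cfg; cfg_d$pathway$variant <- "d448"
  r_d <- cascade_rules(cfg_d)
  expect_lt(r_d$radius[r_d$name == "receptor_tilrr_recruits_myd88"],
            r_wt$radius[r_wt$name == "receptor_tilrr_recruits_myd88"])
  expect_identical(r_d$radius[r_d$name == "receptor_tilrr_recruits_pi3k"],
                   r_wt$radius[r_wt$name == "receptor_tilrr_recruits_pi3k"])
  # ras branch is configurable
  cfg_m <- cfg; cfg_m$pathway$ras_on_branch <- "myd88"
  r_m <- cascade_rules(cfg_m)
  expect_identical(r_m$type_a[r_m$name == "ras_activation"], "MYD88")
})

test_that("stimulation protocol doses receptors and reverts them", {
  geom <- cell_geometry()
  counts <- scale_counts(default_counts(), 0.1)
  set.seed(2)
  pop <- build_initial_population(counts, geom)
  # dose 1 at scale 0.1 activates the full 300-receptor complement
  full <- stimulate(pop, stimulation_protocol(dose = 1), t_min = 0)
  expect_identical(sum(full$state == "ACTIVE" &
                         full$type == "IL1RI_TILRR"), 300L)
  # dose 0 leaves everything inactive
  none <- stimulate(pop, stimulation_protocol(dose = 0), t_min = 0)
  expect_identical(sum(none$state == "ACTIVE" &
                         none$type == "IL1RI_TILRR"), 0L)
  # outside the window receptors revert
  off <- stimulate(full, stimulation_protocol(dose = 1, duration_min = 10),
                   t_min = 20)
  expect_identical(sum(off$state == "ACTIVE" & off$type == "IL1RI_TILRR"),
                   0L)
  expect_error(stimulation_protocol(dose = 1.5), "dose")
})

test_that("IKK phosphorylation frees the NFkB partner and spares the
           cytoskeletal pool", {
  cfg <- quiet_config()
  cfg$pathway$r_phospho <- 0.5
  geom <- cell_geometry()
  # one IKK beside a complex and beside a cytoskeleton-bound IkB
  pop <- tibble::tibble(
    id = 1:5,
    type = c("IKK", "NFKB", "IKB", "CYTOSKELETON_SITE", "IKB"),
    state = c("ACTIVE", "NFKB_BOUND_IKB", "BOUND_NFKB",
              "ACTIVE_IKB_BOUND", "BOUND_CYTOSKELETON"),
    x = c(5, 5.1, 5.1, 5.2, 5.2), y = 0, z = 0,
    partner_id = c(NA, 3L, 2L, 5L, 4L), timer = 0, hits = 0L)
  cfg$motion$D <- 0 # keep them in place
  sim <- simulate_cell(cfg, duration_min = 5, seed = 1, population = pop)
  fin <- sim$population
  # the complexed IkB was phosphorylated and degraded; NFkB freed
  expect_identical(fin$state[fin$type == "NFKB"], "NFKB_FREE")
  expect_false(any(fin$type == "IKB" & fin$state == "BOUND_NFKB"))
  # the cytoskeleton-bound copy is untouched
  expect_identical(sum(fin$type == "IKB" &
                         fin$state == "BOUND_CYTOSKELETON"), 1L)
  expect_identical(sim$timeseries$ev_phospho_cytobound[
    nrow(sim$timeseries)], 0)
})

test_that("transport rules carry the expected cargo set", {
  imp <- nuclear_transport_rule("import")
  expect_setequal(imp$name, c("import_free_nfkb", "import_free_ikb"))
  cfg_no <- default_config(pathway = list(allow_ikb_import = FALSE))
  expect_identical(nuclear_transport_rule("import", cfg_no)$name,
                   "import_free_nfkb")
  exp_rules <- nuclear_transport_rule("export")
  expect_setequal(exp_rules$name,
                  c("export_nfkb_ikb_complex", "export_free_ikb",
                    "export_il8"))
  # import:export receptor ratio at scale 1 mirrors the agent table
  counts <- default_counts()
  expect_identical(
    counts$count[counts$type == "NUCLEAR_IMPORT"] /
      counts$count[counts$type == "NUCLEAR_EXPORT"], 12.5)
})

test_that("no nuclear NFkB means no synthesis ever", {
  cfg <- tiny_config(protocol = list(dose = 0),
                     pathway = list(r_nfkb_dissociator = 0,
                                    r_basal_phospho = 0))
  # fully complexed start: no free NFkB anywhere
  cfg$counts$bound_fraction <- 0.55
  sim <- simulate_cell(cfg, duration_min = 30, seed = 4)
  ts <- sim$timeseries
  # the initial surplus free NFkB is an artifact of the 2/3 partition;
  # with a lower bound fraction every NFkB starts complexed
  expect_identical(ts$nfkb_free[1], 0)
  expect_identical(ts$ev_syn_ikb[nrow(ts)], 0)
  expect_identical(ts$ev_syn_il8[nrow(ts)], 0)
})

test_that("IL-8 is cumulative: the count never decreases", {
  cfg <- default_config(counts = list(scale_factor = 0.05),
                        run = list(duration_min = 40))
  sim <- simulate_cell(cfg, seed = 10)
  expect_true(all(diff(sim$timeseries$il8) >= 0))
})

test_that("deleting a cascade tier abolishes downstream activation", {
  base <- default_config()
  run_il8 <- function(drop_type) {
    counts <- scale_counts(default_counts(), 0.1)
    if (!is.null(drop_type))
      counts$count[counts$type == drop_type] <- 0L
    geom <- cell_geometry()
    set.seed(20)
    pop <- build_initial_population(counts, geom)
    sim <- simulate_cell(base, duration_min = 30, seed = 20,
                         population = pop)
    ts <- sim$timeseries
    c(ikk = ts$ikk_active[nrow(ts)],
      deg = ts$ev_degraded[nrow(ts)])
  }
  with_traf <- run_il8(NULL)
  without_traf <- run_il8("TRAF")
  expect_gt(with_traf["ikk"], 100)
  expect_identical(unname(without_traf["ikk"]), 0)
})
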