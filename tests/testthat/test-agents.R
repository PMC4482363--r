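test_that("default counts reproduce the canonical starting numbers", {
  counts <- default_counts()
  get <- function(tp) counts$count[counts$type == tp]
  expect_identical(get("CYTOSKELETON_SITE"), 600000L)
  expect_identical(get("NFKB"), 20000L)
  expect_identical(get("IKB"), 50000L)
  expect_identical(get("IL8"), 0L)
  expect_identical(get("ACTIN_IKB_DISSOCIATOR"), 70000L)
  expect_identical(get("NUCLEAR_IMPORT"), 2500L)
  expect_identical(get("NUCLEAR_EXPORT"), 200L)
  expect_identical(get("IL1RI_TILRR") + get("IL1RI"), 3000L)
  expect_identical(sort(counts$type), sort(agent_types()))
})

test_that("scaling rounds to nearest, keeps zeros, floors at one", {
  counts <- default_counts()
  expect_identical(scale_counts(counts, 1), counts)
  tenth <- scale_counts(counts, 0.1)
  expect_identical(tenth$count[tenth$type == "CYTOSKELETON_SITE"], 60000L)
  expect_identical(tenth$count[tenth$type == "NFKB"], 2000L)
  expect_identical(tenth$count[tenth$type == "IL8"], 0L)
  tiny <- scale_counts(counts, 1e-5)
  expect_identical(tiny$count[tiny$type == "TRANSCRIPTION_SITE"], 1L)
  expect_identical(tiny$count[tiny$type == "IL8"], 0L)
  expect_error(scale_counts(counts, 0), "positive")
  expect_error(scale_counts(counts, -2), "positive")
})

test_that("initial population implements the resting partition", {
  geom <- cell_geometry()
  counts <- scale_counts(default_counts(), 0.1)
  set.seed(1)
  pop <- build_initial_population(counts, geom, bound_fraction = 2 / 3)
  # 2/3 of 5000 IkB bound to distinct cytoskeleton sites
  bound <- pop[pop$type == "IKB" & pop$state == "BOUND_CYTOSKELETON", ]
  expect_identical(nrow(bound), as.integer(round(2 / 3 * 5000)))
  hosts <- pop[match(bound$partner_id, pop$id), ]
  expect_true(all(hosts$type == "CYTOSKELETON_SITE"))
  expect_identical(anyDuplicated(hosts$id), 0L)
  expect_true(all(hosts$state == "ACTIVE_IKB_BOUND"))
  # bound pairs co-located
  expect_equal(bound$x, hosts$x)
  expect_equal(bound$z, hosts$z)
  # remaining IkB paired 1:1 with NFkB until exhaustion
  cplx <- pop[pop$type == "IKB" & pop$state == "BOUND_NFKB", ]
  expect_identical(nrow(cplx), min(5000L - nrow(bound), 2000L))
  # partner symmetry over the whole population
  linked <- pop[!is.na(pop$partner_id), ]
  back <- pop$partner_id[match(linked$partner_id, pop$id)]
  expect_identical(back, linked$id)
  # everything signalling starts inactive
  for (tp in c("MYD88", "IRAK", "TRAF", "TAK", "RAS", "PI3K", "AKT", "IKK",
               "CASPASE3", "ACTIN_IKB_DISSOCIATOR"))
    expect_true(all(pop$state[pop$type == tp] == "INACTIVE"), label = tp)
  # every state is legal for its type
  states <- agent_states()
  ok <- vapply(seq_len(nrow(pop)),
               function(i) pop$state[i] %in% states[[pop$type[i]]],
               logical(1))
  expect_true(all(ok))
})

test_that("bound_fraction = 0 pairs all NFkB and leaves surplus IkB free", {
  geom <- cell_geometry()
  counts <- scale_counts(default_counts(), 0.1)
  set.seed(1)
  pop <- build_initial_population(counts, geom, bound_fraction = 0)
  expect_identical(sum(pop$type == "NFKB" & pop$state == "NFKB_BOUND_IKB"),
                   2000L)
  expect_identical(sum(pop$type == "IKB" & pop$state == "FREE"), 3000L)
})

test_that("over-committed bound fraction is a configuration error", {
  geom <- cell_geometry()
  counts <- scale_counts(default_counts(), 0.001)
  counts$count[counts$type == "CYTOSKELETON_SITE"] <- 10L
  expect_error(build_initial_population(counts, geom, bound_fraction = 1),
               "exceeds")
})

test_that("state machine accepts named transitions and rejects others", {
  expect_identical(legal_transition("IKB", "FREE", "bind_nfkb"),
                   "BOUND_NFKB")
  # pIkB is terminal
  expect_error(
    legal_transition("IKB", "PHOSPHO_PENDING_DEGRADATION", "bind_nfkb"),
    "illegal")
  expect_error(legal_transition("IKB", "NFKB_FREE", "bind_nfkb"),
               "not legal")
  # every reachable state in the table is in the type's legal set
  tt <- transition_table()
  states <- agent_states()
  for (i in seq_len(nrow(tt))) {
    expect_true(tt$from[i] %in% states[[tt$type[i]]],
                label = paste(tt$type[i], tt$from[i]))
    expect_true(tt$to[i] %in% states[[tt$type[i]]],
                label = paste(tt$type[i], tt$to[i]))
  }
  # transitions are deterministic: one successor per (type, from, event)
  key <- paste(tt$type, tt$from, tt$event)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("population snapshots round-trip through CSV", {
  geom <- cell_geometry()
  counts <- scale_counts(default_counts(), 0.002)
  set.seed(5)
  pop <- build_initial_population(counts, geom)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)
})
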