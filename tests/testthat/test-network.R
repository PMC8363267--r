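test_that("fixture parameter tables load with counts preserved and round-trip", {
  sp <- system.file("extdata", "fixture_species.tsv", package = "erkltp")
  rx <- system.file("extdata", "fixture_reactions.tsv", package = "erkltp")
  net <- load_network(sp, rx, parameterization = "fixture")
  expect_equal(nrow(net$species), 12)
  expect_equal(nrow(net$reactions), 14)
  expect_identical(net$species, build_fixture_network()$species)
  expect_identical(net$reactions, build_fixture_network()$reactions)

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_network_tables(net, f1, f2)
  expect_identical(readLines(f1), readLines(sp))
  expect_identical(readLines(f2), readLines(rx))
})

test_that("schema violations are rejected with informative errors", {
  sp <- data.frame(name = c("A", "B"), initial_nM = c(1, 2))
  expect_error(
    reaction_network(sp, data.frame(label = "r1", reactants = "A + FooKinase",
                                    products = "B", kf = 1)),
    "FooKinase")
  expect_error(
    reaction_network(sp, data.frame(label = "r1", reactants = "A",
                                    products = "B", kf = -1)),
    ">= 0")
  expect_error(
    reaction_network(sp, data.frame(label = "r1", reactants = "2 A + B",
                                    products = "B", kf = 1)),
    "order")
  expect_error(
    reaction_network(data.frame(name = c("A", "A"), initial_nM = c(1, 1)),
                     data.frame(label = "r1", reactants = "A",
                                products = "A", kf = 1)),
    "duplicate")
})

test_that("knockouts zero labeled rates, remove species, scale quantities", {
  net <- fixture()
  # empty config is the identity
  same <- apply_knockout(net, knockout_config())
  expect_identical(same$species, net$species)
  expect_identical(same$reactions, net$reactions)

  ko <- knockout_config(zero_rates = "K_gef_on")
  out <- apply_knockout(net, ko)
  expect_equal(out$reactions$kf[out$reactions$label == "K_gef_on"], 0)
  untouched <- out$reactions$label != "K_gef_on"
  expect_identical(out$reactions[untouched, ], net$reactions[untouched, ])
  expect_identical(net$reactions$kf[net$reactions$label == "K_gef_on"], 0.001)

  ko2 <- knockout_config(remove_species = "Src",
                         scale_quantities = c(PP1 = 2))
  out2 <- apply_knockout(net, ko2)
  expect_equal(out2$species$initial_nM[out2$species$name == "Src"], 0)
  expect_equal(out2$species$initial_nM[out2$species$name == "PP1"], 40)

  # idempotence and commutation on disjoint configs
  expect_identical(apply_knockout(out, ko)$reactions, out$reactions)
  ab <- apply_knockout(apply_knockout(net, ko), ko2)
  ba <- apply_knockout(apply_knockout(net, ko2), ko)
  expect_identical(ab$reactions, ba$reactions)
  expect_identical(ab$species, ba$species)

  expect_error(apply_knockout(net, knockout_config(zero_rates = "K_nope")),
               "valid labels")
})

test_that("conserved moieties match an independent null-space computation", {
  net <- fixture()
  W <- conserved_moieties(net)
  S <- stoichiometry_matrix(net)
  # every reported moiety is in the left null space
  expect_true(all(abs(t(S) %*% W) < 1e-9))
  # independent oracle: rank-nullity on the stoichiometry matrix
  expect_equal(ncol(W), nrow(S) - qr(S)$rank)
  # the expected biological totals are spanned: total ERK, CaMKII, GEF, Src
  for (m in list(c("ERK", "ppERK"), c("CaMKII", "pCaMKII"),
                 c("GEF", "GEFa"), c("Src", "GibgSrc"))) {
    w <- as.numeric(rownames(S) %in% m)
    expect_true(all(abs(t(S) %*% w) < 1e-9), label = paste(m, collapse = "+"))
  }
})

test_that("validate_network flags conservation violations and structure issues", {
  net <- fixture()
  rep0 <- validate_network(net, expected_moieties = list(c("ERK", "ppERK")))
  expect_true(rep0$ok)
  expect_length(rep0$dangling_species, 0)

  # add a creation-from-nothing reaction for ERK: total ERK no longer conserved
  bad <- net
  bad$reactions <- rbind(bad$reactions,
                         data.frame(label = "K_magic", reactants = "",
                                    products = "ERK", kf = 1, kr = NA))
  bad <- reaction_network(bad$species, bad$reactions, volume = bad$volume)
  rep1 <- validate_network(bad, expected_moieties = list(c("ERK", "ppERK")))
  expect_false(rep1$ok)
  expect_match(rep1$conservation_violations, "ERK")

  # dangling species and zero-rate reactions are reported
  sp <- rbind(net$species, data.frame(name = "Orphan", initial_nM = 1,
                                      role = "other"))
  rx <- net$reactions
  rx$kf[rx$label == "K_mkp"] <- 0
  net2 <- reaction_network(sp, rx, volume = 4)
  rep2 <- validate_network(net2)
  expect_identical(rep2$dangling_species, "Orphan")
  expect_true("K_mkp" %in% rep2$zero_rate_reactions)
})
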