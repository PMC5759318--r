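test_that("GAM sums are exact in hundredths with no float drift", {
  expect_identical(compute_gam(36.94, 23.04), 59.98)
  expect_identical(compute_gam(36.94, 8.79), 45.73)
  expect_identical(compute_gam(12.5, 0), 12.5)
  expect_error(compute_gam(-1, 5), "non-negative")
})

test_that("amino-acid ratios equal brute-force letter counting", {
  expect_equal(amino_acid_ratios_from_proteome(c("GG", "AA"))[["G"]],
               0.5)
  r <- amino_acid_ratios_from_proteome("MKV")
  expect_equal(unname(r[c("M", "K", "V")]), rep(1 / 3, 3))
  expect_equal(sum(r), 1)
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prots <- vapply(1:10, function(i)
    paste(sample(aa, sample(20:80, 1), replace = TRUE), collapse = ""),
    character(1))
  got <- amino_acid_ratios_from_proteome(prots)
  all_letters <- strsplit(paste(prots, collapse = ""), "")[[1]]
  want <- table(factor(all_letters, levels = aa)) / length(all_letters)
  expect_equal(unname(got), unname(as.numeric(want)))
  expect_error(amino_acid_ratios_from_proteome(character()), "empty")
  expect_error(amino_acid_ratios_from_proteome(c("MKV", "MXK")),
               "sequence 2")
})

test_that("deoxyribonucleotide ratios follow strand symmetry", {
  expect_equal(unname(dnt_ratios_from_gc(0.5)), rep(0.25, 4))
  expect_equal(dnt_ratios_from_gc(0)[["dA"]], 0.5)
  expect_equal(dnt_ratios_from_gc(0)[["dG"]], 0)
  expect_equal(unname(dnt_ratios_from_gc(0.6)),
               c(0.2, 0.3, 0.3, 0.2))
  expect_error(dnt_ratios_from_gc(1.2), "\\[0, 1\\]")
})

test_that("assembled biomass drains each group's exact mass fraction", {
  comp <- biomass_composition(
    "low",
    mass_fractions = c(protein = 0.6, rna = 0.4),
    monomer_ratios = list(
      protein = c("gly[c]" = 0.5, "ala[c]" = 0.5),
      rna = c("rA[c]" = 1)))
  w <- c("gly[c]" = 0.075, "ala[c]" = 0.089, "rA[c]" = 0.507,
         "atp[c]" = 0.507, "h2o[c]" = 0.018, "adp[c]" = 0.427,
         "pi[c]" = 0.096, "h[c]" = 0.001)
  rxn <- assemble_biomass_reaction(comp, w)
  sto <- rxn$stoichiometry
  monomers <- c("gly[c]", "ala[c]", "rA[c]")
  mass <- sum(abs(sto[monomers]) * w[monomers])
  expect_equal(mass, 1.0, tolerance = 1e-6)
  # per-group masses equal the declared fractions
  expect_equal(sum(abs(sto[c("gly[c]", "ala[c]")]) *
                     w[c("gly[c]", "ala[c]")]), 0.6, tolerance = 1e-9)
  expect_true(all(sto[monomers] < 0))
  expect_equal(rxn$kind, "biomass")
})

test_that("single-monomer group gives the closed-form coefficient", {
  f <- 0.55; w_gly <- 0.075
  comp <- biomass_composition(
    "low", mass_fractions = c(protein = f, other = 0.45),
    monomer_ratios = list(protein = c("gly[c]" = 1),
                          other = c("oth[c]" = 1)))
  rxn <- assemble_biomass_reaction(
    comp, c("gly[c]" = w_gly, "oth[c]" = 0.1))
  expect_equal(rxn$stoichiometry[["gly[c]"]], -f / w_gly)
})

test_that("zero protein fraction leaves no amino-acid terms", {
  comp <- biomass_composition(
    "high", mass_fractions = c(protein = 0, other = 1),
    monomer_ratios = list(other = c("oth[c]" = 1)))
  rxn <- assemble_biomass_reaction(comp, c("oth[c]" = 0.1))
  expect_false(any(grepl("^aa_", names(rxn$stoichiometry))))
})

test_that("the low/high templates differ in GAM by exactly 14.25", {
  lo <- template_biomass("low")
  hi <- template_biomass("high")
  gam_lo <- compute_gam(lo$gam_base, lo$polymerization_cost)
  gam_hi <- compute_gam(hi$gam_base, hi$polymerization_cost)
  expect_identical(gam_lo - gam_hi, 14.25)
  w <- c(stats::setNames(rep(0.11, 20),
                         paste0("aa_", strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                "")[[1]], "[c]")),
         "rA[c]" = 0.5, "rC[c]" = 0.48, "rG[c]" = 0.52, "rU[c]" = 0.49,
         "dA[c]" = 0.49, "dC[c]" = 0.47, "dG[c]" = 0.51, "dT[c]" = 0.48,
         "lipid[c]" = 0.7, "other[c]" = 0.3, "ect-l[c]" = 0.142,
         "hdect[c]" = 0.158)
  r_lo <- assemble_biomass_reaction(lo, w, id = "BIO_L")
  r_hi <- assemble_biomass_reaction(hi, w, id = "BIO_H")
  # energy-term membership is identical; only coefficients move
  energy <- c("atp[c]", "h2o[c]", "adp[c]", "pi[c]", "h[c]")
  expect_true(all(energy %in% names(r_lo$stoichiometry)))
  expect_identical(sort(names(r_lo$stoichiometry)),
                   sort(names(r_hi$stoichiometry)))
  expect_equal(r_hi$stoichiometry[["atp[c]"]] -
                 r_lo$stoichiometry[["atp[c]"]], 14.25)
  expect_error(assemble_biomass_reaction(lo, w[-1]),
               "molecular weight")
})

test_that("composition validation rejects inconsistent inputs", {
  expect_error(biomass_composition(
    "low", c(protein = 1), list(protein = c("g[c]" = 0.9))),
    "not 1")
  expect_error(biomass_composition(
    "low", c(protein = 0.4), list(protein = c("g[c]" = 1))),
    "mass fractions")
  expect_error(biomass_composition(
    "low", c(protein = 1), list(other = c("g[c]" = 1))),
    "no monomer ratios")
})
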