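# Small models with known geometry, built in code at test time.

# 1-D polytope: uptake coupled to a single drain, flux in [0, cap]
box_model <- function(cap = 10) {
  metabolic_model(
    data.frame(id = "x[c]", compartment = "c"),
    data.frame(id = c("EX_in", "R_out"), lb = c(-cap, 0), ub = c(0, cap),
               kind = c("exchange", "metabolic")),
    list(EX_in = c("x[c]" = -1), R_out = c("x[c]" = -1)))
}

# 2-D simplex: v_R1 + v_R2 <= 1, both nonnegative
simplex_model <- function() {
  metabolic_model(
    data.frame(id = "a[c]", compartment = "c"),
    data.frame(id = c("SRC", "R1", "R2"), lb = c(-1, 0, 0),
               ub = c(0, 1, 1),
               kind = c("exchange", "metabolic", "metabolic")),
    list(SRC = c("a[c]" = -1), R1 = c("a[c]" = -1),
         R2 = c("a[c]" = -1)))
}

# linear chain A -> B with stoichiometric 2:1 coupling downstream
coupled_ratio_model <- function(uptake = 10) {
  metabolic_model(
    data.frame(id = c("a[c]", "b[c]"), compartment = "c"),
    data.frame(id = c("EX_a", "R1", "EX_b"), lb = c(-uptake, 0, 0),
               ub = c(0, 1000, 1000),
               kind = c("exchange", "metabolic", "exchange")),
    list(EX_a = c("a[c]" = -1), R1 = c("a[c]" = -1, "b[c]" = 2),
         EX_b = c("b[c]" = -1)))
}

# chain A -> B -> C with the uptake pinned to one value
fixed_chain_model <- function(rate = 5) {
  metabolic_model(
    data.frame(id = c("a[c]", "b[c]", "c1[c]"), compartment = "c"),
    data.frame(id = c("EX_a", "R1", "R2", "EX_c"),
               lb = c(-rate, 0, 0, 0), ub = c(-rate, 1000, 1000, 1000),
               kind = c("exchange", "metabolic", "metabolic",
                        "exchange")),
    list(EX_a = c("a[c]" = -1), R1 = c("a[c]" = -1, "b[c]" = 1),
         R2 = c("b[c]" = -1, "c1[c]" = 1), EX_c = c("c1[c]" = -1)))
}

# wrap a bare matrix as a flux sample set (for statistics-only tests)
as_sample_set <- function(mat, condition = "synthetic", seed = 0L) {
  halofba:::new_flux_sample_set(mat, condition, seed, "synthetic")
}
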