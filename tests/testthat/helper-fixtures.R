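# Shared small fixtures, built in code at test time.

small_primary <- function(seed = 7, n_species = 12, n_families = 3, ...) {
  generate_primary(fixture_config(n_species = n_species,
                                  n_families = n_families, seed = seed, ...))
}

# Table-1-style excerpt: three classes plus two nominal and one metrical
# attribute worth of values, used for literal parsing checks.
table1_rows <- function() {
  tibble::tribble(
    ~name,               ~class, ~cap_diameter, ~cap_shape,    ~season,
    "Fly Agaric",        "p",    "[10:20]",     "[x, f]",      "[u, a, w]",
    "Panther Cap",       "p",    "[5:10]",      "[p, x]",      "[u, a]",
    "False Panther Cap", "p",    "[10:15]",     "[x, f]",      "[u, a]",
    "Common Morel",      "e",    "[3:8]",       "[p, c, o]",   "[s]",
    "Jelly Babies",      "p",    "[1:1.5]",     "[x, f, s]",   "[u, a]"
  )
}

# A secondary table where the class is an XOR of two binary nominal
# variables: only non-linearly separable in one-hot space. The two XOR
# variables get full {t, f} sets so they vary within species; the other
# nominal attributes are held constant so the XOR pair carries the only
# class signal, with the species-varying metrical traits as noise.
xor_secondary <- function(seed = 9, n_species = 8, n_per_species = 250) {
  sch <- mushroom_schema("primary")
  pt <- generate_primary(fixture_config(n_species = n_species,
                                        n_families = min(4, n_species),
                                        seed = seed))
  for (v in sch$name[sch$kind == "nominal" & sch$role == "attribute"]) {
    pt[[v]] <- rep(list(schema_codes(sch, v)[1]), nrow(pt))
  }
  pt[["does-bruise-or-bleed"]] <- rep(list(c("t", "f")), nrow(pt))
  pt[["has-ring"]] <- rep(list(c("t", "f")), nrow(pt))
  sec <- simulate_table(pt, simulation_config(n_per_species = n_per_species,
                                              seed = seed + 1))
  sec <- impute_most_frequent(sec)
  generate_nonlinear_labels(sec, list(
    type = "xor", variables = c("does-bruise-or-bleed", "has-ring"),
    codes = c("t", "t")))
}

linear_secondary <- function(seed = 9, n_species = 40, n_per_species = 60) {
  pt <- generate_primary(fixture_config(n_species = n_species,
                                        n_families = min(8, n_species),
                                        seed = seed))
  pt[["does-bruise-or-bleed"]] <- rep(list(c("t", "f")), nrow(pt))
  sec <- simulate_table(pt, simulation_config(n_per_species = n_per_species,
                                              seed = seed + 1))
  sec <- impute_most_frequent(sec)
  generate_nonlinear_labels(sec, list(
    type = "linear", variables = "does-bruise-or-bleed", codes = "t"))
}
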