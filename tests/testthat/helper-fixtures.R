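## Shared fixtures: built in code at test time, cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

full_model <- function() cached("full_model", build_model())

rubisco_model <- function(condition = "LC*")
  cached(paste0("rubisco_model_", condition),
         build_model(read_catalogue(), standard_scenarios()$rubisco,
                     condition))

rubisco_cone <- function(condition = "LC*")
  cached(paste0("rubisco_cone_", condition),
         build_constraints(rubisco_model(condition), condition = condition))

rubisco_samples <- function(condition = "LC*", n = 20, seed = 404)
  cached(paste0("rubisco_samples_", condition, "_", n, "_", seed),
         sample_fluxes(rubisco_cone(condition), n, seed = seed,
                       warmup = 300, thin = 30))

synthetic_measurements <- function()
  cached("synthetic_measurements",
         read_measurements(cbc_data_file("measurements")))

reference_truth <- function(condition = "LC*", seed = 11)
  cached(paste0("truth_", condition, "_", seed),
         generate_ground_truth(standard_scenarios()$rubisco, condition,
                               seed = seed))

## a minimal single-enzyme, two-compartment catalogue written to disk
toy_paths <- function() {
  cached("toy_paths", {
    cat_path <- tempfile(fileext = ".tsv")
    writeLines(c(
      "id\tequation\tenzyme\tkind\tcompartments",
      "R1\tA -> B\tE1\tenzymatic\tboth",
      "T_A\tA[s] <-> A[p]\t-\ttransport\t-",
      "T_B\tB[s] <-> B[p]\t-\ttransport\t-",
      "X_A_IN\tA[c] -> A[s]\t-\texchange\t-",
      "X_B_OUT\tB[s] -> B[c]\t-\texchange\t-"), cat_path)
    moi_path <- tempfile(fileext = ".tsv")
    writeLines(c("metabolite\tcarbon\tphosphate", "A\t1\t0", "B\t1\t0"),
               moi_path)
    part_path <- tempfile(fileext = ".tsv")
    writeLines(c("enzyme\tcondition\tfraction_mean\tfraction_se",
                 "E1\tLC\t0.6\t0.05", "E1\tHC\t0.2\t0.05"), part_path)
    list(catalogue = cat_path, moieties = moi_path, partitions = part_path)
  })
}

toy_model <- function() {
  cached("toy_model", {
    p <- toy_paths()
    build_model(read_catalogue(p$catalogue), scenario("toy", "E1"), "LC",
                moieties = read_moieties(p$moieties))
  })
}

toy_cone <- function() {
  cached("toy_cone", {
    p <- toy_paths()
    build_constraints(toy_model(), read_partitions(p$partitions),
                      condition = "LC", fixed = c(X_A_IN = 10))
  })
}

free_bounds <- function(model, lo = 0.5, hi = 50)
  data.frame(species = model$species$id, c_min = lo, c_max = hi,
             measured = FALSE, stringsAsFactors = FALSE)
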