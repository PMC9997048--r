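#' Per-variable privacy budget
#'
#' Under sequential composition an overall privacy factor `epsilon` split
#' equally over `p` released variables gives each variable a Laplace noise
#' scale of `p / epsilon` (e.g. scale 17 for 17 variables at `epsilon = 1`).
#'
#' @param epsilon overall privacy factor (`> 0`).
#' @param p number of released variables.
#' @return An object of class `flush_budget` with elements `epsilon`, `p`,
#'   `scale = p / epsilon` and a `consumed` ledger of variables perturbed.
#' @export
privacy_budget <- function(epsilon, p) {
  check_scalar(epsilon, "epsilon", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  structure(list(epsilon = epsilon, p = as.integer(p), scale = p / epsilon,
                 consumed = character(0)),
            class = "flush_budget")
}

#' @export
print.flush_budget <- function(x, ...) {
  cat(sprintf(
    "<privacy budget: epsilon %g over %d variables, per-variable Laplace scale %g; %d consumed>\n",
    x$epsilon, x$p, x$scale, length(x$consumed)))
  invisible(x)
}

.flush_ledger <- new.env(parent = emptyenv())

ledger_lookup <- function(hash, ledger_path) {
  if (!is.null(ledger_path) && file.exists(ledger_path)) {
    led <- jsonlite::read_json(ledger_path, simplifyVector = TRUE)
    if (!is.null(led[[hash]])) return(led[[hash]])
  }
  .flush_ledger[[hash]]
}

ledger_record <- function(hash, entry, ledger_path) {
  .flush_ledger[[hash]] <- entry
  if (!is.null(ledger_path)) {
    led <- if (file.exists(ledger_path))
      jsonlite::read_json(ledger_path, simplifyVector = TRUE) else list()
    led[[hash]] <- entry
    jsonlite::write_json(led, ledger_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(entry)
}

#' Release an epsilon-differentially-private perturbed copy of a table
#'
#' Splits the data once (seeded) into a holdout part and a release part, fits
#' the conditional chain on the holdout only, and perturbs the release part
#' with Laplace noise at per-variable scale `p / epsilon`. The holdout is
#' never emitted: it exists solely to estimate the target distributions so
#' that the mechanism depends on released records only through their own
#' values plus independent noise. The split is fixed once selected — a
#' content hash of the dataset is kept in a ledger (in-memory, and on disk
#' when `ledger_path` is given), and re-invoking with a different split
#' configuration on the same data is an error.
#'
#' @param data data frame of raw records.
#' @param schema a `flush_schema`.
#' @param epsilon overall privacy factor.
#' @param holdout_fraction fraction of rows assigned to the holdout, in (0,1).
#' @param m number of perturbed copies.
#' @param seed integer root seed (drives the split and the perturbation).
#' @param ledger_path optional JSON file persisting the split ledger across
#'   sessions.
#' @return A list of class `flush_private` with elements `perturbed` (a
#'   `flush_perturbed`), `budget` (a `flush_budget`), `release_rows` (indices
#'   of released records) and `hash`.
#' @export
privatize <- function(data, schema, epsilon, holdout_fraction = 0.5,
                      m = 1L, seed = NULL, ledger_path = NULL) {
  check_scalar(epsilon, "epsilon", positive = TRUE)
  check_scalar(holdout_fraction, "holdout_fraction")
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop_df("`holdout_fraction` must lie strictly inside (0, 1)")
  vars <- schema_vars(schema)
  n <- nrow(data)
  n_hold <- round(n * holdout_fraction)
  if (n_hold < 2L || n - n_hold < 1L)
    stop_df("too few rows for a non-degenerate holdout/release split")

  hash <- dataset_hash(data)
  entry <- list(holdout_fraction = holdout_fraction,
                split_seed = derive_seed(seed, "split"))
  prev <- ledger_lookup(hash, ledger_path)
  if (!is.null(prev) && !identical(
        lapply(prev, as.numeric)[c("holdout_fraction", "split_seed")],
        lapply(entry, as.numeric)[c("holdout_fraction", "split_seed")]))
    stop_df("the holdout split for this dataset is fixed once selected; ",
            "re-invocation with a different split is not permitted")
  ledger_record(hash, entry, ledger_path)

  hold_idx <- with_seed(entry$split_seed, sample.int(n, n_hold))
  holdout <- data[hold_idx, , drop = FALSE]
  release <- data[-hold_idx, , drop = FALSE]

  chain <- fit_conditional_chain(holdout, schema)
  plan <- perturbation_plan(
    noise = make_noise_model("laplace", length(vars) / epsilon),
    m = m, seed = derive_seed(seed, "perturb"),
    dp_mode = TRUE, epsilon = epsilon, keep_noise = TRUE)
  pert <- perturb_multivariate(release, chain, plan)
  structure(list(perturbed = pert, budget = pert$budget,
                 release_rows = setdiff(seq_len(n), hold_idx), hash = hash),
            class = "flush_private")
}

#' @export
print.flush_private <- function(x, ...) {
  print(x$budget)
  print(x$perturbed)
  invisible(x)
}
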