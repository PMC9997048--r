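#' Variable schema for mixed-type tabular data
#'
#' Declares the type of every column to be perturbed: `"continuous"` and
#' `"empirical"` columns go through smoothed empirical (or model-based)
#' distribution functions; `"binary"` and `"nominal"` columns are perturbed
#' on a fixed category-to-integer coding and mapped back to categories, so
#' the CDF machinery applies to an ordered support. The coding (the `levels`
#' entry) is persisted with the schema so releases are reproducible.
#'
#' @param types named character vector mapping column names to types.
#' @param levels named list of level vectors for nominal/binary columns;
#'   inferred from the data at fit time when omitted.
#' @param weight optional name of a survey-weight column (not perturbed; used
#'   to weight the fitted distributions).
#' @return An object of class `flush_schema`.
#' @export
flush_schema <- function(types, levels = list(), weight = NULL) {
  ok <- c("continuous", "empirical", "binary", "nominal")
  if (is.null(names(types)) || any(!nzchar(names(types))))
    stop_df("`types` must be a named character vector")
  bad <- setdiff(unique(types), ok)
  if (length(bad))
    stop_df("unsupported variable type(s): ", paste(bad, collapse = ", "))
  structure(list(types = types, levels = levels, weight = weight),
            class = "flush_schema")
}

#' Read or write a schema as JSON
#' @param path file path.
#' @param schema a `flush_schema`.
#' @export
read_schema <- function(path) {
  raw <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  types <- vapply(raw$columns, function(co) co$type, character(1))
  names(types) <- vapply(raw$columns, function(co) co$name, character(1))
  lev <- Filter(Negate(is.null),
                stats::setNames(lapply(raw$columns, function(co) unlist(co$levels)),
                                names(types)))
  flush_schema(types, levels = lev, weight = raw$weight %||% NULL)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  cols <- lapply(names(schema$types), function(nm) {
    co <- list(name = nm, type = unname(schema$types[[nm]]))
    if (!is.null(schema$levels[[nm]])) co$levels <- as.list(schema$levels[[nm]])
    co
  })
  jsonlite::write_json(list(columns = cols, weight = schema$weight), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

schema_vars <- function(schema) setdiff(names(schema$types), schema$weight)

is_discrete_type <- function(type) type %in% c("binary", "nominal")

# Coerce a raw column to the internal representation used by the chain:
# numeric for continuous/empirical, factor with persisted levels otherwise.
code_column <- function(x, type, levels = NULL) {
  if (is_discrete_type(type)) {
    lev <- levels %||% sort(unique(as.character(x)))
    f <- factor(as.character(x), levels = lev)
    if (anyNA(f)) stop_df("column contains levels absent from the schema")
    f
  } else {
    if (!is.numeric(x)) stop_df("continuous/empirical columns must be numeric")
    x
  }
}

# Restore a perturbed internal value to the column's original class.
decode_column <- function(codes, type, levels, template) {
  if (!is_discrete_type(type)) return(codes)
  vals <- levels[codes]
  if (is.numeric(template)) as.numeric(vals)
  else if (is.factor(template)) factor(vals, levels = levels)
  else vals
}

#' Fit a chain-rule conditional model for multivariate perturbation
#'
#' Factorizes the joint law of the ordered variables as a marginal for the
#' first variable times a conditional law for each later variable given its
#' perturbed prefix. The marginal is a smoothed (weighted) empirical CDF (on
#' category codes for discrete types). For positions `l >= 2`, a
#' continuous/empirical variable gets a linear location model on the prefix
#' with a smoothed empirical CDF of its residuals; a binary variable gets a
#' logistic model and a nominal variable a multinomial-logit model, whose
#' fitted class probabilities define the conditional discrete target. Each
#' fitted builder is a pure function of the prefix and its parameters.
#'
#' @param data data frame containing every schema column; at least 2 rows,
#'   no missing values.
#' @param schema a `flush_schema`.
#' @param order optional character vector ordering the perturbed variables;
#'   defaults to schema order. The first variable carries the record
#'   identifier through rank matching.
#' @return An object of class `flush_chain`.
#' @export
fit_conditional_chain <- function(data, schema, order = NULL) {
  if (!inherits(schema, "flush_schema")) stop_df("`schema` must be a flush_schema")
  order <- order %||% schema_vars(schema)
  missing_cols <- setdiff(c(order, schema$weight), names(data))
  if (length(missing_cols))
    stop_df("columns missing from data: ", paste(missing_cols, collapse = ", "))
  if (!all(order %in% names(schema$types)))
    stop_df("`order` contains columns not covered by the schema")
  if (nrow(data) < 2L) stop_df("need at least 2 rows to fit the chain")
  if (anyNA(data[order])) stop_df("missing values are not supported")
  w <- if (!is.null(schema$weight)) data[[schema$weight]] else NULL

  levels_used <- schema$levels
  coded <- data
  for (v in order) {
    ty <- schema$types[[v]]
    coded[[v]] <- code_column(data[[v]], ty, levels_used[[v]])
    if (is_discrete_type(ty) && is.null(levels_used[[v]]))
      levels_used[[v]] <- levels(coded[[v]])
  }

  models <- vector("list", length(order))
  names(models) <- order
  for (l in seq_along(order)) {
    v <- order[l]; ty <- schema$types[[v]]
    x <- coded[[v]]
    if (l == 1L) {
      models[[l]] <- if (is_discrete_type(ty)) {
        probs <- tapply(w %||% rep(1, length(x)), x, sum)
        probs[is.na(probs)] <- 0
        list(type = ty, kind = "marginal_discrete",
             probs = as.numeric(probs) / sum(probs))
      } else {
        list(type = ty, kind = "marginal_continuous",
             target = fit_smoothed_cdf(x, w))
      }
    } else {
      pref <- coded[order[seq_len(l - 1L)]]
      df <- cbind(.y = x, pref)
      models[[l]] <- if (ty == "nominal") {
        fit <- nnet::multinom(.y ~ ., data = df, weights = w,
                              trace = FALSE, maxit = 300)
        list(type = ty, kind = "multinomial", fit = fit,
             lev = levels(x))
      } else if (ty == "binary") {
        fit <- suppressWarnings(
          glm(.y ~ ., data = df, family = binomial(), weights = w))
        list(type = ty, kind = "logistic", fit = fit, lev = levels(x))
      } else {
        fit <- lm(.y ~ ., data = df, weights = w)
        list(type = ty, kind = "location",
             fit = fit, resid = fit_smoothed_cdf(residuals(fit), w))
      }
    }
  }
  structure(list(order = order, schema = schema, models = models,
                 levels = levels_used, n_fit = nrow(data),
                 templates = lapply(data[order], head, 1L),
                 row_keys = row_keys(data[order])),
            class = "flush_chain")
}

#' @export
print.flush_chain <- function(x, ...) {
  cat(sprintf("<conditional chain: %d variables (%s), fitted on %d rows>\n",
              length(x$order), paste(x$order, collapse = " -> "), x$n_fit))
  invisible(x)
}

# Class-probability matrix (rows = records) for a discrete chain component.
chain_class_probs <- function(model, prefix, n) {
  if (model$kind == "marginal_discrete") {
    matrix(model$probs, n, length(model$probs), byrow = TRUE)
  } else if (model$kind == "logistic") {
    p1 <- predict(model$fit, newdata = prefix, type = "response")
    cbind(1 - p1, p1)
  } else {
    P <- predict(model$fit, newdata = prefix, type = "probs")
    if (is.null(dim(P))) P <- cbind(1 - P, P) # two-level degenerate case
    P
  }
}

# Map uniform-scale values v (one per record) through the component's
# conditional target. Continuous components return numeric values; discrete
# components return category codes (the generalized inverse of the discrete
# conditional CDF, which reproduces the fitted class law exactly).
chain_perturb_component <- function(chain, l, prefix, v) {
  model <- chain$models[[l]]
  n <- length(v)
  if (model$kind == "marginal_continuous") {
    target_quantile(model$target, v)
  } else if (model$kind == "location") {
    mu <- predict(model$fit, newdata = prefix)
    mu + target_quantile(model$resid, v)
  } else {
    P <- chain_class_probs(model, prefix, n)
    cum <- t(apply(P, 1L, cumsum))
    cum[, ncol(cum)] <- 1
    rowSums(cum < v) + 1L
  }
}

#' Conditional target distribution for one record
#'
#' Exposes the fitted conditional law `R^(l)` of variable `l` given a single
#' prefix of perturbed values as a [new_target_distribution()] object, mainly
#' for inspection and testing of the chain's builder contract.
#'
#' @param chain a `flush_chain`.
#' @param l position in the chain (1-based).
#' @param prefix_row one-row data frame of perturbed prefix values (ignored
#'   for `l = 1`).
#' @return A `flush_target`.
#' @export
conditional_target <- function(chain, l, prefix_row = NULL) {
  model <- chain$models[[l]]
  if (model$kind == "marginal_continuous") return(model$target)
  if (model$kind == "location") {
    mu <- as.numeric(predict(model$fit, newdata = prefix_row))
    res <- model$resid
    return(new_target_distribution(
      cdf = function(x) target_cdf(res, x - mu),
      quantile = function(u) mu + target_quantile(res, u),
      support = "continuous",
      label = sprintf("conditional location + residual ecdf (mu = %.4g)", mu)))
  }
  P <- chain_class_probs(model, prefix_row, 1L)
  smoothed_discrete_target(as.numeric(P[1L, ]))
}
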