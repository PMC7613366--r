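#' Min-max scaling to \[0, 1\]
#'
#' Linear rescaling of each variable by its fitted range:
#' `N = (x - x_min)/(x_max - x_min)`, the standard preparation before PLS and
#' kernel modelling. The scaler stores the per-variable minima and maxima so
#' that scaled predictions can be mapped back into original units (mg/kg for
#' concentrations). Applied to new data, values outside the fitted range map
#' outside \[0, 1\]; that is intentional when the scaler is fitted on a
#' training set only.
#'
#' A constant variable (`x_max == x_min`) cannot be rescaled; its scaled
#' values are set to 0 with a warning.
#'
#' @param x Numeric vector, matrix or data frame (variables in columns).
#' @return `fit_minmax()` returns a `minmax_scaler`; `transform_minmax()` and
#'   `invert_minmax()` return an object shaped like their input.
#' @examples
#' sc <- fit_minmax(c(2, 4, 6))
#' transform_minmax(sc, c(2, 4, 6))  # 0 0.5 1
#' @export
fit_minmax <- function(x) {
  m <- .as_num_matrix(x)
  if (nrow(m) < 2) stop("need >= 2 values to fit a min-max scaler", call. = FALSE)
  x_min <- apply(m, 2, min)
  x_max <- apply(m, 2, max)
  if (any(x_max == x_min)) {
    warning("constant variable(s): ",
            paste(colnames(m)[x_max == x_min], collapse = ", "),
            "; their scaled values are set to 0", call. = FALSE)
  }
  structure(list(x_min = x_min, x_max = x_max,
                 vector_input = is.null(dim(x))),
            class = "minmax_scaler")
}

.as_num_matrix <- function(x) {
  if (is.null(dim(x))) {
    m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "x"))
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' @rdname fit_minmax
#' @param scaler A fitted `minmax_scaler`.
#' @export
transform_minmax <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  m <- .as_num_matrix(x)
  rng <- scaler$x_max - scaler$x_min
  out <- sweep(m, 2, scaler$x_min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  .match_shape(out, x)
}

#' @rdname fit_minmax
#' @export
invert_minmax <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  m <- .as_num_matrix(x)
  out <- sweep(m, 2, scaler$x_max - scaler$x_min, "*")
  out <- sweep(out, 2, scaler$x_min, "+")
  .match_shape(out, x)
}

.match_shape <- function(m, like) {
  if (is.null(dim(like))) as.numeric(m) else {
    dimnames(m) <- dimnames(as.matrix(like))
    m
  }
}

#' @rdname fit_minmax
#' @return `fit_transform_minmax()` returns `list(scaler, scaled)`.
#' @export
fit_transform_minmax <- function(x) {
  scaler <- fit_minmax(x)
  list(scaler = scaler, scaled = transform_minmax(scaler, x))
}

#' Serialize / restore a min-max scaler as JSON
#'
#' Scaler parameters are written alongside model reports so that scaled
#' predictions remain convertible to original units later.
#'
#' @param scaler A `minmax_scaler`.
#' @param path File path.
#' @return `write_scaler_json()` returns `path` invisibly;
#'   `read_scaler_json()` returns a `minmax_scaler`.
#' @export
write_scaler_json <- function(scaler, path) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  jsonlite::write_json(list(x_min = as.list(scaler$x_min),
                            x_max = as.list(scaler$x_max),
                            vector_input = scaler$vector_input),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler_json
#' @export
read_scaler_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_min = unlist(obj$x_min), x_max = unlist(obj$x_max),
                 vector_input = isTRUE(obj$vector_input)),
            class = "minmax_scaler")
}

#' Random 70/30 train/test split
#'
#' Randomly partitions sample ids into a training and a testing set with
#' `round(fraction * n)` training samples, optionally stratified so that each
#' stratum (typically the treatment level) contributes proportionally to the
#' training set. Per-stratum training counts are allocated by largest
#' remainder so the overall training size is exactly `round(fraction * n)`.
#' If any stratum holds fewer than 2 samples the split falls back to
#' unstratified sampling with a warning. Deterministic given `seed`.
#'
#' @param sample_ids Character vector of unique sample ids (`n >= 3`).
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer RNG seed (required).
#' @param strata Optional vector (same length) of stratum labels.
#'
#' @return `list(train = <ids>, test = <ids>)`; disjoint, union = all ids.
#' @examples
#' split_train_test(as.character(1:84), seed = 1)  # 59 train / 25 test
#' @export
split_train_test <- function(sample_ids, fraction = 0.7, seed, strata = NULL) {
  stopifnot(length(sample_ids) >= 3, !anyDuplicated(sample_ids),
            fraction > 0, fraction < 1)
  if (missing(seed)) stop("`seed` is required for a reproducible split",
                          call. = FALSE)
  n_train <- round(fraction * length(sample_ids))
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(sample_ids))
    sizes <- table(strata)
    if (any(sizes < 2)) {
      warning("stratum with < 2 samples; falling back to unstratified split",
              call. = FALSE)
      strata <- NULL
    }
  }
  train <- .with_seed(seed, {
    if (is.null(strata)) {
      sample(sample_ids, n_train)
    } else {
      labs <- unique(strata)
      quota <- fraction * tabulate(factor(strata, levels = labs))
      alloc <- floor(quota)
      rem <- n_train - sum(alloc)
      if (rem > 0) {
        extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1
      } else if (rem < 0) {
        cut <- order(quota - alloc)[seq_len(-rem)]
        alloc[cut] <- alloc[cut] - 1
      }
      unlist(lapply(seq_along(labs), function(i) {
        ids <- sample_ids[strata == labs[i]]
        sample(ids, min(alloc[i], length(ids)))
      }))
    }
  })
  list(train = train, test = setdiff(sample_ids, train))
}
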