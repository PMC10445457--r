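## Mixed continuous/categorical optimization domains and their numeric
## encoding: min-max scaling to [0, 1] for continuous variables, one-hot
## indicator blocks for categorical ones. The encoding round-trips
## losslessly, which the surrogate model and the acquisition search rely on.

#' Define a mixed optimization domain
#'
#' @param continuous Named list of `c(low, high)` bounds, e.g.
#'   `list(temperature_C = c(50, 100), residence_time_min = c(5, 60))`.
#' @param categorical Named list of character level vectors, e.g.
#'   `list(catalyst = c("tBuBrettPhos Pd G3", "tBuXPhos Pd G3"))`.
#' @return Object of class `domain_spec`.
#' @export
#' @examples
#' d <- domain_spec(continuous = list(x = c(0, 1)),
#'                  categorical = list(cat = c("A", "B")))
#' encode_condition(list(x = 0.5, cat = "B"), d)
domain_spec <- function(continuous = list(), categorical = list()) {
  if (length(continuous) + length(categorical) == 0)
    stop("domain is empty", call. = FALSE)
  nms <- c(names(continuous), names(categorical))
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("all domain variables need unique names", call. = FALSE)
  for (nm in names(continuous)) {
    b <- continuous[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop(sprintf("continuous variable '%s' needs bounds c(low, high) with low < high", nm),
           call. = FALSE)
  }
  for (nm in names(categorical)) {
    lv <- categorical[[nm]]
    if (length(lv) < 1 || anyDuplicated(lv))
      stop(sprintf("categorical variable '%s' needs >= 1 distinct level", nm),
           call. = FALSE)
    categorical[[nm]] <- as.character(lv)
  }
  d <- list(continuous = continuous, categorical = categorical)
  class(d) <- "domain_spec"
  d
}

#' @export
print.domain_spec <- function(x, ...) {
  cat("<domain_spec>\n")
  for (nm in names(x$continuous))
    cat(sprintf("  %s: [%g, %g]\n", nm, x$continuous[[nm]][1],
                x$continuous[[nm]][2]))
  for (nm in names(x$categorical))
    cat(sprintf("  %s: {%s}\n", nm, paste(x$categorical[[nm]], collapse = ", ")))
  invisible(x)
}

#' Encoded dimensionality of a domain
#' @param d A [domain_spec()].
#' @return Integer: number of continuous variables plus total one-hot levels.
#' @export
n_encoded <- function(d) {
  length(d$continuous) + sum(lengths(d$categorical))
}

#' Encode a condition record as a numeric vector
#'
#' Continuous variables are min-max scaled to `[0, 1]`; each categorical
#' variable becomes a one-hot indicator block.
#'
#' @param x Named list or one-row `data.frame` with one entry per domain
#'   variable.
#' @param d A [domain_spec()].
#' @return Named numeric vector of length [n_encoded()].
#' @export
encode_condition <- function(x, d) {
  x <- as.list(x)
  out <- numeric(0)
  for (nm in names(d$continuous)) {
    v <- x[[nm]]
    b <- d$continuous[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1)
      stop(sprintf("missing or non-numeric value for '%s'", nm), call. = FALSE)
    if (v < b[1] - 1e-9 || v > b[2] + 1e-9)
      stop(sprintf("'%s' = %g outside domain [%g, %g]", nm, v, b[1], b[2]),
           call. = FALSE)
    out <- c(out, setNames((v - b[1]) / (b[2] - b[1]), nm))
  }
  for (nm in names(d$categorical)) {
    lv <- d$categorical[[nm]]
    v <- as.character(x[[nm]])
    if (length(v) != 1 || !v %in% lv)
      stop(sprintf("unknown level '%s' for categorical '%s'",
                   paste(v, collapse = ","), nm), call. = FALSE)
    block <- as.numeric(lv == v)
    out <- c(out, setNames(block, paste0(nm, "=", lv)))
  }
  out
}

#' Decode an encoded vector back to a condition record
#'
#' Inverse of [encode_condition()]: continuous entries are rescaled to their
#' bounds, each one-hot block maps to its maximal level.
#'
#' @param v Numeric vector of length [n_encoded()].
#' @param d A [domain_spec()].
#' @return Named list (a condition record).
#' @export
decode_condition <- function(v, d) {
  out <- list()
  i <- 1L
  for (nm in names(d$continuous)) {
    b <- d$continuous[[nm]]
    out[[nm]] <- b[1] + min(max(v[i], 0), 1) * (b[2] - b[1])
    i <- i + 1L
  }
  for (nm in names(d$categorical)) {
    lv <- d$categorical[[nm]]
    block <- v[i:(i + length(lv) - 1L)]
    out[[nm]] <- lv[which.max(block)]
    i <- i + length(lv)
  }
  out
}

#' Encode a design table row-wise
#' @param X `data.frame` of condition records.
#' @param d A [domain_spec()].
#' @return Numeric matrix, one encoded row per condition.
#' @export
encode_design <- function(X, d) {
  p <- n_encoded(d)
  M <- vapply(seq_len(nrow(X)),
              function(i) encode_condition(X[i, , drop = FALSE], d),
              numeric(p))
  if (p == 1) matrix(M, ncol = 1) else t(M)
}

## internal: uniform random conditions (encoded space)
.random_encoded <- function(d, n) {
  p_cont <- length(d$continuous)
  M <- matrix(0, n, n_encoded(d))
  if (p_cont > 0) M[, seq_len(p_cont)] <- runif(n * p_cont)
  j <- p_cont
  for (nm in names(d$categorical)) {
    lv <- d$categorical[[nm]]
    pick <- sample.int(length(lv), n, replace = TRUE)
    M[cbind(seq_len(n), j + pick)] <- 1
    j <- j + length(lv)
  }
  M
}

## internal: space-filling initial design (Latin hypercube on the continuous
## block, uniform categorical levels)
.lhs_encoded <- function(d, n) {
  p_cont <- length(d$continuous)
  M <- matrix(0, n, n_encoded(d))
  if (p_cont > 0) M[, seq_len(p_cont)] <- lhs::randomLHS(n, p_cont)
  j <- p_cont
  for (nm in names(d$categorical)) {
    lv <- d$categorical[[nm]]
    pick <- sample.int(length(lv), n, replace = TRUE)
    M[cbind(seq_len(n), j + pick)] <- 1
    j <- j + length(lv)
  }
  M
}

## internal: decode rows of an encoded matrix into a data.frame
.decode_rows <- function(M, d) {
  recs <- lapply(seq_len(nrow(M)), function(i) {
    as.data.frame(decode_condition(M[i, ], d), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
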