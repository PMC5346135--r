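#' Trapezoidal membership function
#'
#' A trapezoid rising linearly from `a` to `b`, flat at grade 1 on `[b, c]`,
#' and falling linearly from `c` to `d`. Degenerate corners (`a == b` or
#' `c == d`) give shoulder or triangular shapes.
#'
#' @param a,b,c,d Breakpoints in the parameter's physical units,
#'   with `a <= b <= c <= d`.
#' @return An object of class `trap_mf`.
#' @examples
#' mf <- trap_mf(8, 10, 20, 25)
#' membership_grade(mf, c(9, 12, 30))
#' @export
trap_mf <- function(a, b, c, d) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1,
            is.finite(a), is.finite(b), is.finite(c), is.finite(d))
  if (!(a <= b && b <= c && c <= d)) {
    stop("trap_mf breakpoints must satisfy a <= b <= c <= d", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d), class = "trap_mf")
}

#' @export
print.trap_mf <- function(x, ...) {
  cat(sprintf("<trap_mf a=%g b=%g c=%g d=%g>\n", x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate a trapezoidal membership function
#'
#' Piecewise-linear evaluation; a total, continuous function of `x` with
#' values in `[0, 1]`, equal to 1 on the plateau `[b, c]` and 0 outside
#' the open support `(a, d)`.
#'
#' @param mf A [trap_mf()].
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of grades in `[0, 1]`.
#' @export
membership_grade <- function(mf, x) {
  stopifnot(inherits(mf, "trap_mf"), is.numeric(x))
  g <- numeric(length(x))
  g[x >= mf$b & x <= mf$c] <- 1
  if (mf$b > mf$a) {
    ix <- x > mf$a & x < mf$b
    g[ix] <- (x[ix] - mf$a) / (mf$b - mf$a)
  }
  if (mf$d > mf$c) {
    ix <- x > mf$c & x < mf$d
    g[ix] <- (mf$d - x[ix]) / (mf$d - mf$c)
  }
  g[is.na(x)] <- NA_real_
  g
}

#' Fuzzy partition of a parameter's physical range
#'
#' An ordered, named family of trapezoids covering `range`. Partitions are
#' required to be sum-to-one: at every point of the range the grades over
#' all labels add to exactly 1, so adjacent sets share their transition
#' edges (the falling edge `(c, d)` of one set is the rising edge `(a, b)`
#' of the next) and non-adjacent sets have disjoint support.
#'
#' @param parameter Parameter name (e.g. `"etco2"`).
#' @param sets Named list of [trap_mf()], ordered from the lowest label to
#'   the highest (e.g. `VL, L, N, H, VH`).
#' @param range Length-2 numeric, the declared physical range.
#' @return An object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(parameter, sets, range) {
  stopifnot(is.character(parameter), length(parameter) == 1,
            is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(vapply(sets, inherits, logical(1), "trap_mf")),
            is.numeric(range), length(range) == 2, range[1] < range[2])
  p <- structure(list(parameter = parameter, sets = sets,
                      range = as.numeric(range)),
                 class = "fuzzy_partition")
  validate_partition(p)
  p
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition '%s' on [%g, %g]>\n",
              x$parameter, x$range[1], x$range[2]))
  for (lab in names(x$sets)) {
    m <- x$sets[[lab]]
    cat(sprintf("  %-3s (%g, %g, %g, %g)\n", lab, m$a, m$b, m$c, m$d))
  }
  invisible(x)
}

# Structural checks: first set saturates the range bottom, last the top,
# consecutive sets share transition edges, so the partition is sum-to-one
# by construction. A numeric spot-check guards against degenerate input.
validate_partition <- function(p) {
  s <- p$sets
  k <- length(s)
  if (s[[1]]$a != p$range[1] || s[[1]]$b != p$range[1]) {
    stop(sprintf("partition '%s': first set must plateau from the range start",
                 p$parameter), call. = FALSE)
  }
  if (s[[k]]$c != p$range[2] || s[[k]]$d != p$range[2]) {
    stop(sprintf("partition '%s': last set must plateau to the range end",
                 p$parameter), call. = FALSE)
  }
  for (i in seq_len(k - 1)) {
    if (s[[i]]$c != s[[i + 1]]$a || s[[i]]$d != s[[i + 1]]$b) {
      stop(sprintf(
        "partition '%s': sets '%s' and '%s' must share their transition edge",
        p$parameter, names(s)[i], names(s)[i + 1]), call. = FALSE)
    }
    if (s[[i]]$d <= s[[i]]$c) {
      stop(sprintf("partition '%s': sets '%s'/'%s' must overlap",
                   p$parameter, names(s)[i], names(s)[i + 1]), call. = FALSE)
    }
  }
  xs <- seq(p$range[1], p$range[2], length.out = 257)
  tot <- rowSums(grade_matrix(xs, p))
  if (any(abs(tot - 1) > 1e-9)) {
    stop(sprintf("partition '%s' is not sum-to-one", p$parameter),
         call. = FALSE)
  }
  invisible(p)
}

# n x labels grade matrix; x is clamped to the declared range first.
grade_matrix <- function(x, partition) {
  x <- pmin(pmax(x, partition$range[1]), partition$range[2])
  m <- vapply(partition$sets, membership_grade, numeric(length(x)), x = x)
  if (length(x) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(partition$sets)))
  m
}

#' Fuzzify a crisp value
#'
#' Clamps `x` to the partition's declared range and returns the grade of
#' membership in every labeled set. Grades sum to 1.
#'
#' @param x A single finite numeric value.
#' @param partition A [fuzzy_partition()].
#' @return Named numeric vector of grades, one per label.
#' @export
fuzzify <- function(x, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid_sample(sprintf("cannot fuzzify non-finite value for '%s'",
                                partition$parameter))
  }
  drop(grade_matrix(x, partition)[1, ])
}

stop_invalid_sample <- function(msg) {
  stop(structure(class = c("ipindex_invalid_sample", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate fuzzy rules over fuzzified grades
#'
#' Mamdani rule evaluation with `min` for AND and `max` for aggregation:
#' a rule's activation is the minimum of its antecedent grades, and each
#' consequent level's activation is the maximum over all rules sharing it.
#'
#' @param grades Named list, one element per parameter, each a named
#'   numeric vector of label grades (as from [fuzzify()]).
#' @param rules Data frame with one column per antecedent parameter
#'   (values are labels, `NA` = don't care) and an integer `consequent`
#'   column with values in 1..10.
#' @return Named numeric vector of activations for levels `"1"`..`"10"`.
#' @export
evaluate_rules <- function(grades, rules) {
  stopifnot(is.list(grades), is.data.frame(rules), "consequent" %in% names(rules))
  pars <- setdiff(names(rules), "consequent")
  if (!all(pars %in% names(grades))) {
    stop("rules reference parameters without grades: ",
         paste(setdiff(pars, names(grades)), collapse = ", "), call. = FALSE)
  }
  if (!all(rules$consequent %in% 1:10)) {
    stop("rule consequents must be integers in 1..10", call. = FALSE)
  }
  act <- stats::setNames(numeric(10), as.character(1:10))
  for (i in seq_len(nrow(rules))) {
    a <- 1
    for (p in pars) {
      lab <- rules[[p]][i]
      if (is.na(lab)) next
      if (!lab %in% names(grades[[p]])) {
        stop(sprintf("rule %d: unknown label '%s' for parameter '%s'",
                     i, lab, p), call. = FALSE)
      }
      a <- min(a, grades[[p]][[lab]])
    }
    k <- as.character(rules$consequent[i])
    act[k] <- max(act[k], a)
  }
  act
}

# Output universe for the IPI score: ten symmetric unit-base triangles
# centred at the integer levels 1..10, supports [k-1/2, k+1/2], inside
# the axis [0.5, 10.5]. Non-overlapping supports make the Mamdani
# aggregate (max of clipped triangles) equal their sum almost everywhere.
output_levels <- function() 1:10

# Area of a unit triangle (base 1, height 1) clipped at activation a.
clipped_area <- function(a) 0.5 * a * (2 - a)

#' Centroid-of-area defuzzification
#'
#' Mamdani min-implication: each consequent triangle is clipped at its
#' level's activation, the clipped shapes are aggregated with `max`, and
#' the centroid of the aggregate is returned. Because the unit-base
#' triangles centred at 1..10 have non-overlapping supports the centroid
#' has the exact closed form
#' `sum(k * a_k (2 - a_k)) / sum(a_k (2 - a_k))`.
#'
#' @param activations Named numeric vector of activations in `[0, 1]`
#'   (names are levels `"1"`..`"10"`; missing levels count as 0).
#' @return The crisp centroid, a value in `[1, 10]`.
#' @export
defuzzify_centroid <- function(activations) {
  stopifnot(is.numeric(activations))
  a <- stats::setNames(numeric(10), as.character(1:10))
  if (is.null(names(activations))) {
    stopifnot(length(activations) == 10)
    a[] <- activations
  } else {
    stopifnot(all(names(activations) %in% names(a)))
    a[names(activations)] <- activations
  }
  if (any(a < 0 | a > 1)) stop("activations must lie in [0, 1]", call. = FALSE)
  if (all(a == 0)) {
    stop(structure(class = c("ipindex_no_rule_fired", "error", "condition"),
                   list(message = "no rule fired: all activations are zero",
                        call = sys.call())))
  }
  g <- clipped_area(a)
  v <- sum(output_levels() * g) / sum(g)
  min(max(v, 1), 10)
}

# Vectorised centroid over an n x 10 activation matrix (one row per
# sample). Rows with no activation yield NA.
defuzzify_centroid_matrix <- function(act) {
  g <- 0.5 * act * (2 - act)
  den <- rowSums(g)
  num <- as.vector(g %*% output_levels())
  v <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(v, 1), 10)
}

# Round-half-up to the nearest integer (the display convention for the
# reported IPI; R's round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)
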