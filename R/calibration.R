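#' @name calibration
#' @title Shipped IPI calibration
#'
#' @description
#' The IPI model is specified by (i) a sum-to-one trapezoidal partition per
#' vital-sign channel, (ii) a 5x5 rule matrix giving the consequent IPI
#' level for each RR x PetCO2 label pair under normal SpO2, (iii) a
#' per-label SpO2 consequent drop realizing the desaturation effect, and
#' (iv) two secondary pulse-rate rules that subtract one point when the
#' pulse contradicts the ventilatory picture. PetCO2 and SpO2 partitions
#' and the rule matrix are shared across age modes; RR and PR partitions
#' shift with age. The shipped breakpoints are calibrated so that the
#' reference behaviours hold exactly: all-normal vitals score 10, apneic
#' extremes score 1, (RR 12, PetCO2 26) under normal SpO2/PR scores 8 and
#' drops to 5 at SpO2 90.
NULL

#' Age modes
#'
#' @return Character vector of supported age modes. Scoring is not defined
#'   below 1 year of age.
#' @export
age_modes <- function() c("adult", "ped_1_3", "ped_3_6", "ped_6_12")

labels5 <- function() c("VL", "L", "N", "H", "VH")
labels3 <- function() c("L", "N", "H")

partition_from_breaks <- function(parameter, breaks, range) {
  sets <- lapply(breaks, function(q) trap_mf(q[1], q[2], q[3], q[4]))
  fuzzy_partition(parameter, sets, range)
}

# Breakpoint quadruples per channel. PetCO2 (mmHg) and SpO2 (%) are
# age-invariant; RR (breaths/min) and PR (beats/min) normal plateaus rise
# with decreasing age per standard pediatric vital-sign tables.
default_breaks <- function(mode) {
  etco2 <- list(VL = c(0, 0, 5, 15),  L = c(5, 15, 28, 33),
                N = c(28, 33, 43, 48), H = c(43, 48, 55, 60),
                VH = c(55, 60, 100, 100))
  # The High set sits above the measurable end of the axis: saturation is
  # bounded at 100 % and supra-normal oxygenation carries no penalty, so H
  # never attains positive grade at physiological values and the score is
  # constant across the normal plateau up to 100.
  spo2 <- list(L = c(0, 0, 85, 93), N = c(85, 93, 100, 105),
               H = c(100, 105, 110, 110))
  rr <- switch(mode,
    adult    = list(VL = c(0, 0, 4, 8),   L = c(4, 8, 10, 12),
                    N = c(10, 12, 20, 24), H = c(20, 24, 30, 35),
                    VH = c(30, 35, 60, 60)),
    ped_1_3  = list(VL = c(0, 0, 10, 14), L = c(10, 14, 18, 20),
                    N = c(18, 20, 28, 32), H = c(28, 32, 40, 46),
                    VH = c(40, 46, 60, 60)),
    ped_3_6  = list(VL = c(0, 0, 8, 12),  L = c(8, 12, 16, 18),
                    N = c(16, 18, 26, 30), H = c(26, 30, 38, 44),
                    VH = c(38, 44, 60, 60)),
    ped_6_12 = list(VL = c(0, 0, 6, 10),  L = c(6, 10, 13, 15),
                    N = c(13, 15, 22, 26), H = c(22, 26, 34, 40),
                    VH = c(34, 40, 60, 60)),
    stop(sprintf("unknown age mode '%s'", mode), call. = FALSE))
  pr <- switch(mode,
    adult    = list(L = c(0, 0, 45, 55),  N = c(45, 55, 100, 115),
                    H = c(100, 115, 250, 250)),
    ped_1_3  = list(L = c(0, 0, 75, 90),  N = c(75, 90, 150, 165),
                    H = c(150, 165, 250, 250)),
    ped_3_6  = list(L = c(0, 0, 65, 80),  N = c(65, 80, 140, 155),
                    H = c(140, 155, 250, 250)),
    ped_6_12 = list(L = c(0, 0, 55, 70),  N = c(55, 70, 120, 135),
                    H = c(120, 135, 250, 250)))
  list(etco2 = etco2, rr = rr, spo2 = spo2, pr = pr)
}

channel_ranges <- function() {
  list(etco2 = c(0, 100), rr = c(0, 60), spo2 = c(0, 100), pr = c(0, 250))
}

# Declared fuzzification axes; SpO2 extends past the measurable range so
# the High set can live above 100 (see default_breaks()).
axis_ranges <- function() {
  r <- channel_ranges()
  r$spo2 <- c(0, 110)
  r
}

#' Default fuzzy partitions for an age mode
#'
#' @param mode One of [age_modes()].
#' @return Named list of [fuzzy_partition()] objects for `etco2`, `rr`,
#'   `spo2` and `pr`.
#' @examples
#' p <- default_partitions("adult")
#' fuzzify(98, p$spo2)  # fully Normal
#' @export
default_partitions <- function(mode = "adult") {
  mode <- match.arg(mode, age_modes())
  br <- default_breaks(mode)
  rg <- axis_ranges()
  mapply(function(ch, b) partition_from_breaks(ch, b, rg[[ch]]),
         names(br), br, SIMPLIFY = FALSE)
}

# Consequent IPI level for each RR (rows, VL..VH) x PetCO2 (cols, VL..VH)
# label pair assuming normal SpO2 and PR. Anchored at all-normal -> 10,
# apnea corner -> 1, (N, L) -> 8 and (VH, VH) -> 2; every row and column
# is non-increasing away from the normal label.
default_rule_matrix <- function() {
  m <- matrix(c(
    # etco2: VL  L   N   H   VH
              1,  1,  2,  1,  1,   # rr VL
              3,  5,  6,  4,  3,   # rr L
              5,  8, 10,  8,  5,   # rr N
              4,  6,  8,  6,  3,   # rr H
              3,  4,  5,  3,  2),  # rr VH
    nrow = 5, byrow = TRUE,
    dimnames = list(rr = labels5(), etco2 = labels5()))
  storage.mode(m) <- "integer"
  m
}

# Consequent drop per SpO2 label (desaturation effect); results are
# floored at level 1. Cells already inside the intervention band (at or
# below spo2_preserve_max) reflect ventilatory collapse that desaturation
# cannot meaningfully worsen and keep their consequent unchanged.
default_spo2_drop <- function() c(L = 7L, N = 0L, H = 0L)

default_spo2_preserve_max <- function() 3L

dropped_consequent <- function(base, drop, preserve_max) {
  if (base <= preserve_max) base else max(base - drop, 1L)
}

# Secondary PR rules: each subtracts one point, graded by the fuzzy
# degree of its compound condition (see apply_pr_adjustment()).
default_pr_rules <- function() {
  list(
    list(pr = "L", etco2 = c("H", "VH"), rr = c("H", "VH"), subtract = 1),
    list(pr = "H", etco2 = c("L", "VL"), rr = c("L", "VL"), subtract = 1)
  )
}

#' Default rule base
#'
#' Expands the RR x PetCO2 matrix and the SpO2 drop into the full primary
#' rule table (one rule per RR x PetCO2 x SpO2 label combination) and
#' attaches the secondary PR rules.
#'
#' @param rule_matrix 5x5 integer matrix of consequents (rows RR labels,
#'   columns PetCO2 labels).
#' @param spo2_drop Named integer vector of consequent drops per SpO2 label.
#' @param pr_rules List of secondary PR adjustment rules.
#' @return An object of class `ipi_rulebase` with elements `rules` (data
#'   frame `rr`, `etco2`, `spo2`, `consequent`; `spo2 = NA` marks a
#'   "don't care" antecedent), `matrix`, `spo2_drop` and `pr_rules`.
#'   Every RR x PetCO2 x SpO2 label combination is covered by exactly
#'   one rule.
#' @export
default_rulebase <- function(rule_matrix = default_rule_matrix(),
                             spo2_drop = default_spo2_drop(),
                             pr_rules = default_pr_rules(),
                             spo2_preserve_max = default_spo2_preserve_max()) {
  stopifnot(is.matrix(rule_matrix), all(dim(rule_matrix) == c(5, 5)),
            all(rule_matrix %in% 1:10),
            all(labels3() %in% names(spo2_drop)), all(spo2_drop >= 0),
            spo2_preserve_max >= 1)
  # One rule per RR x PetCO2 x SpO2 combination, except that cells whose
  # consequent is independent of the SpO2 label collapse to a single rule
  # with a "don't care" SpO2 antecedent (NA). Keeping an SpO2 clause there
  # would cap the rule's activation at the transition grade and make the
  # score rise as saturation falls through a transition zone.
  rows <- list()
  for (rl in labels5()) for (el in labels5()) {
    cons <- vapply(labels3(), function(sl) {
      dropped_consequent(rule_matrix[rl, el], spo2_drop[[sl]],
                         spo2_preserve_max)
    }, integer(1))
    if (length(unique(cons)) == 1L) {
      rows[[length(rows) + 1]] <- data.frame(
        rr = rl, etco2 = el, spo2 = NA_character_,
        consequent = cons[[1]], stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        rr = rl, etco2 = el, spo2 = labels3(),
        consequent = as.integer(cons), stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  rb <- structure(list(rules = grid, matrix = rule_matrix,
                       spo2_drop = spo2_drop,
                       spo2_preserve_max = as.integer(spo2_preserve_max),
                       pr_rules = pr_rules),
                  class = "ipi_rulebase")
  validate_rulebase(rb)
  rb
}

# Effective consequent for a crisp label combination (honours "don't
# care" SpO2 antecedents).
rule_consequent <- function(rb, rr, etco2, spo2) {
  r <- rb$rules
  hit <- r$rr == rr & r$etco2 == etco2 & (is.na(r$spo2) | r$spo2 == spo2)
  r$consequent[hit]
}

# Coverage and monotonicity checks, run at load time.
validate_rulebase <- function(rb) {
  for (rl in labels5()) for (el in labels5()) {
    cv <- vapply(labels3(), function(sl) {
      k <- rule_consequent(rb, rl, el, sl)
      if (length(k) != 1L) {
        stop(sprintf(
          "rule base must map (%s, %s, %s) to exactly one consequent (found %d)",
          rl, el, sl, length(k)), call. = FALSE)
      }
      k
    }, integer(1))  # ordered L, N, H
    if (cv[["L"]] > cv[["N"]] || cv[["N"]] > cv[["H"]]) {
      stop("consequents must be non-increasing as SpO2 labels decrease",
           call. = FALSE)
    }
  }
  # rows/columns of the matrix non-increasing away from N
  m <- rb$matrix
  mono_away <- function(v) all(diff(v[3:5]) <= 0) && all(diff(rev(v[1:3])) <= 0)
  if (!all(apply(m, 1, mono_away)) || !all(apply(m, 2, mono_away))) {
    stop("rule matrix must be non-increasing away from the normal label",
         call. = FALSE)
  }
  invisible(rb)
}

#' @export
print.ipi_rulebase <- function(x, ...) {
  cat("<ipi_rulebase> RR x PetCO2 consequents (SpO2 N):\n")
  print(x$matrix)
  cat(sprintf("SpO2 drop: %s; %d secondary PR rules\n",
              paste(names(x$spo2_drop), x$spo2_drop, sep = "=", collapse = " "),
              length(x$pr_rules)))
  invisible(x)
}

#' Assemble a calibration for an age mode
#'
#' @param mode One of [age_modes()].
#' @param partitions Channel partitions; defaults to [default_partitions()].
#' @param rulebase Rule base; defaults to [default_rulebase()].
#' @return Object of class `ipi_calibration`.
#' @export
ipi_calibration <- function(mode = "adult",
                            partitions = default_partitions(mode),
                            rulebase = default_rulebase()) {
  mode <- match.arg(mode, age_modes())
  stopifnot(setequal(names(partitions), c("etco2", "rr", "spo2", "pr")),
            inherits(rulebase, "ipi_rulebase"))
  lapply(partitions, validate_partition)
  structure(list(mode = mode, partitions = partitions, rulebase = rulebase),
            class = "ipi_calibration")
}

#' @export
print.ipi_calibration <- function(x, ...) {
  cat(sprintf("<ipi_calibration mode='%s'>\n", x$mode))
  for (p in x$partitions) print(p)
  print(x$rulebase)
  invisible(x)
}

#' Write a calibration to a YAML config file
#'
#' @param calibration An `ipi_calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "ipi_calibration"))
  brk <- lapply(calibration$partitions, function(p) {
    lapply(p$sets, function(m) c(m$a, m$b, m$c, m$d))
  })
  obj <- list(
    mode = calibration$mode,
    ranges = axis_ranges(),
    partitions = brk,
    rule_matrix = apply(calibration$rulebase$matrix, 1, as.integer,
                        simplify = FALSE),
    spo2_drop = as.list(calibration$rulebase$spo2_drop),
    spo2_preserve_max = calibration$rulebase$spo2_preserve_max,
    pr_rules = lapply(calibration$rulebase$pr_rules, function(r) {
      list(pr = r$pr, etco2 = as.list(r$etco2), rr = as.list(r$rr),
           subtract = r$subtract)
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a calibration from a YAML config file
#'
#' The file must supply per-channel breakpoint quadruples, the 5x5 rule
#' matrix, the SpO2 drop table and the secondary PR rules; structural and
#' monotonicity validation is applied on load.
#'
#' @param path YAML file as written by [write_calibration()]. `NULL`
#'   returns the shipped defaults for `mode`.
#' @param mode Age mode used when `path` is `NULL`.
#' @return An `ipi_calibration`.
#' @export
read_calibration <- function(path = NULL, mode = "adult") {
  if (is.null(path)) return(ipi_calibration(mode))
  obj <- yaml::read_yaml(path)
  need <- c("mode", "partitions", "rule_matrix", "spo2_drop", "pr_rules")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("calibration file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rg <- axis_ranges()
  parts <- mapply(function(ch, brk) {
    partition_from_breaks(ch, lapply(brk, as.numeric), rg[[ch]])
  }, names(obj$partitions), obj$partitions, SIMPLIFY = FALSE)
  m <- do.call(rbind, lapply(obj$rule_matrix, as.integer))
  dimnames(m) <- list(rr = labels5(), etco2 = labels5())
  pr_rules <- lapply(obj$pr_rules, function(r) {
    list(pr = r$pr, etco2 = unlist(r$etco2), rr = unlist(r$rr),
         subtract = as.numeric(r$subtract))
  })
  drop <- stats::setNames(as.integer(unlist(obj$spo2_drop)), names(obj$spo2_drop))
  preserve <- if (is.null(obj$spo2_preserve_max)) {
    default_spo2_preserve_max()
  } else as.integer(obj$spo2_preserve_max)
  rb <- default_rulebase(rule_matrix = m, spo2_drop = drop,
                         pr_rules = pr_rules, spo2_preserve_max = preserve)
  ipi_calibration(obj$mode, partitions = parts, rulebase = rb)
}
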