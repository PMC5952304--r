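# Study-level outcome statistics: exact Fisher test, Mann-Whitney,
# 2^-ddCt relative quantification, neurodegeneration classification,
# incidence/frequency reductions and weight trajectories.

.as_table2x2 <- function(table) {
  x <- if (is.matrix(table)) as.vector(t(table)) else as.numeric(table)
  if (length(x) != 4L) stop("a 2x2 table needs exactly 4 counts")
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("2x2 table counts must be non-negative integers")
  }
  x <- as.integer(round(x))
  if (sum(x) < 1L) stop("2x2 table must contain at least one observation")
  x
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric point
#' probabilities, at fixed margins, of all tables no more probable than
#' the observed one (the convention of mainstream statistical software;
#' a relative tolerance of 1e-7 guards the equality comparison).
#'
#' @param table A 2x2 matrix (rows = groups, columns = outcome yes/no) or
#'   a length-4 vector `c(a, b, c, d)` in row-major order.
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(c(10, 0, 3, 8))   # SRS incidence, 10/10 vs 3/11
#' @export
fisher_exact_two_sided <- function(table) {
  x <- .as_table2x2(table)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m1 <- a + b          # row-1 margin
  m2 <- c + d          # row-2 margin
  n1 <- a + c          # column-1 margin
  support <- max(0L, n1 - m2):min(n1, m1)
  dens <- stats::dhyper(support, m1, m2, n1)
  d_obs <- stats::dhyper(a, m1, m2, n1)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The two-sided
#' p-value is exact (doubled smaller tail of the full permutation
#' distribution of U, capped at 1) when `min(n) <= 8` and the combined
#' sample size is at most 25; otherwise a normal approximation with tie
#' correction (no continuity correction) is used. The exact path handles
#' ties by enumerating the rank-sum distribution over the observed
#' midrank multiset.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   path.
#' @return A list with `U` (for the first sample), `p.value` and
#'   `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- min(n1, n2) <= 8 && n <= 25
  if (exact) {
    # distribution of the doubled rank sum over all C(n, n1) subsets,
    # by subset-sum dynamic programming (midranks doubled -> integers)
    d <- as.integer(round(2 * r))
    total <- sum(d)
    # counts[k+1, s+1] = number of size-k subsets with doubled-rank sum s
    counts <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
    counts[1L, 1L] <- 1
    for (v in d) {
      kmax <- n1
      for (k in kmax:1) {
        nz <- which(counts[k, ] > 0)
        if (length(nz)) {
          counts[k + 1L, nz + v] <- counts[k + 1L, nz + v] + counts[k, nz]
        }
      }
    }
    dist <- counts[n1 + 1L, ]
    sums <- (seq_along(dist) - 1L)
    u_vals <- sums / 2 - n1 * (n1 + 1) / 2
    w <- dist[dist > 0]
    u <- u_vals[dist > 0]
    tot <- sum(w)
    p_lo <- sum(w[u <= U + 1e-9]) / tot
    p_hi <- sum(w[u >= U - 1e-9]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p.value = p, method = method)
}

#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, the target cycle threshold is referenced to the
#' geometric mean of the housekeeping-gene CTs
#' (`dCt = Ct_target - geomean(Ct_housekeeping)`); ddCt subtracts the
#' arithmetic mean dCt of the control group, and the fold change is
#' `2^-ddCt`.
#'
#' @param plate A data.frame with columns `sample`, `group`, `gene`,
#'   `ct` (one row per sample x gene; CT in cycles, > 0).
#' @param target Target gene name.
#' @param housekeeping Character vector of internal control genes
#'   (default beta-actin, GAPDH, HPRT1).
#' @param control_group Label of the reference group (default
#'   `"control"`).
#' @return A list with `per_sample` (sample, group, dct, ddct, fold) and
#'   `group_mean` (group, mean_fold).
#' @export
ddct_fold_change <- function(plate, target,
                             housekeeping = c("ACTB", "GAPDH", "HPRT1"),
                             control_group = "control") {
  stopifnot(is.data.frame(plate),
            all(c("sample", "group", "gene", "ct") %in% names(plate)))
  if (any(plate$ct <= 0)) stop("CT values must be positive")
  samples <- unique(plate$sample)
  per <- lapply(samples, function(s) {
    sub <- plate[plate$sample == s, ]
    hk <- sub$ct[match(housekeeping, sub$gene)]
    if (anyNA(hk)) {
      stop("sample ", s, " is missing housekeeping CT(s): ",
           paste(housekeeping[is.na(hk)], collapse = ", "))
    }
    tg <- sub$ct[match(target, sub$gene)]
    if (is.na(tg)) stop("sample ", s, " is missing target gene ", target)
    data.frame(sample = s, group = sub$group[1],
               dct = tg - geometric_mean(hk))
  })
  per <- do.call(rbind, per)
  ctrl <- per$dct[per$group == control_group]
  if (!length(ctrl)) stop("no samples in control group '", control_group, "'")
  per$ddct <- per$dct - mean(ctrl)
  per$fold <- 2^(-per$ddct)
  gm <- stats::aggregate(fold ~ group, per, mean)
  names(gm)[2] <- "mean_fold"
  list(per_sample = per, group_mean = gm)
}

#' FluoroJade B protection classification
#'
#' A hippocampal subregion is classified as degenerating when more than
#' 10 (equivalently, 11 or more) FJB-positive cells are counted per
#' section; otherwise protected.
#'
#' @param count_per_section Non-negative cell count(s).
#' @return Character vector, `"protected"` or `"degenerating"`.
#' @export
fjb_protection_class <- function(count_per_section) {
  if (any(count_per_section < 0)) stop("cell counts must be non-negative")
  ifelse(count_per_section > 10, "degenerating", "protected")
}

#' Group outcome counts
#'
#' @param label Group label.
#' @param n_subjects Number of animals in the group.
#' @param n_positive Number of animals positive for the outcome.
#' @param events_total Total event count across the group (e.g., number
#'   of seizures).
#' @return A `group_outcome` object.
#' @export
group_outcome <- function(label, n_subjects, n_positive = 0,
                          events_total = 0) {
  stopifnot(n_subjects >= 1, n_positive >= 0, n_positive <= n_subjects,
            events_total >= 0)
  structure(list(label = label, n_subjects = n_subjects,
                 n_positive = n_positive, events_total = events_total),
            class = "group_outcome")
}

#' Percent reduction in outcome incidence
#'
#' `100 * (1 - incidence(treated) / incidence(reference))`, rounded to
#' the nearest integer percent (the presentation convention for group
#' incidences).
#'
#' @param treated,reference [group_outcome()] objects; the reference
#'   incidence must be positive.
#' @return Integer percent reduction.
#' @examples
#' incidence_reduction(group_outcome("urethane", 11, 3),
#'                     group_outcome("diazepam", 10, 10))
#' @export
incidence_reduction <- function(treated, reference) {
  stopifnot(inherits(treated, "group_outcome"),
            inherits(reference, "group_outcome"))
  ref <- reference$n_positive / reference$n_subjects
  if (ref <= 0) stop("reference incidence is zero; reduction undefined")
  trt <- treated$n_positive / treated$n_subjects
  round(100 * (1 - trt / ref))
}

#' Percent reduction in per-subject event frequency
#'
#' By default the per-subject event rate
#' (`events_total / n_subjects`) is compared:
#' `100 * (1 - rate(treated) / rate(reference))`. `method =
#' "total_count"` instead compares raw event totals, the alternative
#' arithmetic for the same headline number.
#'
#' @param treated,reference [group_outcome()] objects; the reference
#'   rate must be positive.
#' @param method `"per_subject_rate"` (default) or `"total_count"`.
#' @return Percent reduction (not rounded).
#' @export
frequency_reduction <- function(treated, reference,
                                method = c("per_subject_rate",
                                           "total_count")) {
  stopifnot(inherits(treated, "group_outcome"),
            inherits(reference, "group_outcome"))
  method <- match.arg(method)
  if (reference$events_total <= 0) {
    stop("reference event rate is zero; reduction undefined")
  }
  ratio <- if (method == "per_subject_rate") {
    (treated$events_total / treated$n_subjects) /
      (reference$events_total / reference$n_subjects)
  } else {
    treated$events_total / reference$events_total
  }
  100 * (1 - ratio)
}

#' Body mass as percent of day 0
#'
#' @param mass Numeric vector of per-day body masses; the first element
#'   is day 0 and must be positive.
#' @return `100 * mass / mass[1]`, same length as `mass`.
#' @export
percent_of_day0 <- function(mass) {
  mass <- as.numeric(mass)
  if (!length(mass) || mass[1] <= 0) {
    stop("day-0 mass must be positive")
  }
  100 * mass / mass[1]
}
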