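COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two datasets to a common effect allele per variant. For each
#' exposure variant found in the outcome set:
#' \itemize{
#'   \item identical allele orientation: kept as-is;
#'   \item effect/other alleles swapped: the outcome beta is negated and its
#'     allele frequency replaced by `1 - eaf` (`sign-flipped`);
#'   \item alleles reported on the opposite strand (both complemented):
#'     rescued by complementing, possibly combined with a swap
#'     (`strand-flipped` / `strand-sign-flipped`);
#'   \item palindromic pair (A/T or C/G): dropped unconditionally
#'     (`dropped-palindromic`) — strand is ambiguous for such variants
#'     across datasets, and no frequency-based inference is attempted;
#'   \item alleles not reconcilable by swap or strand flip:
#'     `dropped-allele-mismatch`.
#' }
#' Exposure variants absent from the outcome are `dropped-unmatched`. The
#' exposure orientation is never altered. The per-variant action log is part
#' of the returned object; actions over all input exposure variants
#' partition them exactly.
#'
#' @param exposure,outcome Summary-statistics data.frames (canonical
#'   columns); variant ids must be unique within each.
#' @param exposure_name,outcome_name Trait labels carried into results.
#' @return An object of class `harmonized_set`: a list with `data` (columns
#'   `SNP`, `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`),
#'   `exposure_name`, `outcome_name`, and `log` (columns `SNP`, `action`).
#' @export
harmonize_pair <- function(exposure, outcome,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  if (anyDuplicated(exposure$SNP)) {
    stop("duplicate variant id(s) in exposure: ",
         paste(utils::head(unique(exposure$SNP[duplicated(exposure$SNP)]), 3),
               collapse = ", "))
  }
  if (anyDuplicated(outcome$SNP)) {
    stop("duplicate variant id(s) in outcome: ",
         paste(utils::head(unique(outcome$SNP[duplicated(outcome$SNP)]), 3),
               collapse = ", "))
  }
  m <- match(exposure$SNP, outcome$SNP)
  J <- nrow(exposure)
  action <- character(J)
  beta_y <- se_y <- eaf_y <- rep(NA_real_, J)

  for (i in seq_len(J)) {
    j <- m[i]
    if (is.na(j)) {
      action[i] <- "dropped-unmatched"
      next
    }
    ea_x <- exposure$effect_allele[i]
    oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]
    oa_y <- outcome$other_allele[j]
    if (is_palindromic(ea_x, oa_x) || is_palindromic(ea_y, oa_y)) {
      action[i] <- "dropped-palindromic"
      next
    }
    flip <- NA  # TRUE = negate outcome beta
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"; flip <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      action[i] <- "sign-flipped"; flip <- TRUE
    } else {
      # same variant reported on the opposite strand
      ea_c <- unname(COMPLEMENT[ea_y]); oa_c <- unname(COMPLEMENT[oa_y])
      if (ea_c == ea_x && oa_c == oa_x) {
        action[i] <- "strand-flipped"; flip <- FALSE
      } else if (ea_c == oa_x && oa_c == ea_x) {
        action[i] <- "strand-sign-flipped"; flip <- TRUE
      } else {
        action[i] <- "dropped-allele-mismatch"
        next
      }
    }
    beta_y[i] <- if (flip) -outcome$beta[j] else outcome$beta[j]
    se_y[i] <- outcome$se[j]
    ef <- outcome$eaf[j]
    eaf_y[i] <- if (flip && !is.na(ef)) 1 - ef else ef
  }

  kept <- !startsWith(action, "dropped")
  data <- data.frame(
    SNP = exposure$SNP[kept],
    effect_allele = exposure$effect_allele[kept],
    other_allele = exposure$other_allele[kept],
    beta_exposure = exposure$beta[kept],
    se_exposure = exposure$se[kept],
    eaf_exposure = exposure$eaf[kept],
    beta_outcome = beta_y[kept],
    se_outcome = se_y[kept],
    eaf_outcome = eaf_y[kept],
    stringsAsFactors = FALSE
  )
  rownames(data) <- NULL
  structure(list(data = data,
                 exposure_name = exposure_name,
                 outcome_name = outcome_name,
                 log = data.frame(SNP = exposure$SNP, action = action,
                                  stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' Number of harmonized variants
#' @param x A `harmonized_set`.
#' @return Integer count of retained variants.
#' @export
n_snps <- function(x) {
  stopifnot(inherits(x, "harmonized_set"))
  nrow(x$data)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s vs %s: %d variant(s) retained of %d\n",
              x$exposure_name, x$outcome_name, nrow(x$data), nrow(x$log)))
  invisible(x)
}

#' Summarize harmonization actions
#'
#' @param set A `harmonized_set`.
#' @return A named integer vector of counts over all defined actions
#'   (kept, sign-flipped, strand-flipped, strand-sign-flipped,
#'   dropped-palindromic, dropped-unmatched, dropped-allele-mismatch);
#'   counts sum to the number of input exposure variants.
#' @export
harmonization_report <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  actions <- c("kept", "sign-flipped", "strand-flipped",
               "strand-sign-flipped", "dropped-palindromic",
               "dropped-unmatched", "dropped-allele-mismatch")
  counts <- stats::setNames(integer(length(actions)), actions)
  tab <- table(set$log$action)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Build a harmonized_set directly from aligned effect arrays (used by the
# simulator-driven tests and estimator examples where allele bookkeeping is
# irrelevant).
harmonized_from_arrays <- function(beta_exposure, se_exposure,
                                   beta_outcome, se_outcome,
                                   variant_ids = NULL,
                                   exposure_name = "exposure",
                                   outcome_name = "outcome") {
  J <- length(beta_exposure)
  stopifnot(length(se_exposure) == J, length(beta_outcome) == J,
            length(se_outcome) == J, all(se_exposure > 0),
            all(se_outcome > 0))
  if (is.null(variant_ids)) {
    variant_ids <- as.character(seq_len(J))
    variant_ids[] <- paste0("rs", variant_ids)
  }
  data <- data.frame(SNP = variant_ids,
                     effect_allele = rep("A", J), other_allele = rep("G", J),
                     beta_exposure = beta_exposure,
                     se_exposure = se_exposure,
                     eaf_exposure = rep(NA_real_, J),
                     beta_outcome = beta_outcome,
                     se_outcome = se_outcome,
                     eaf_outcome = rep(NA_real_, J),
                     stringsAsFactors = FALSE)
  structure(list(data = data, exposure_name = exposure_name,
                 outcome_name = outcome_name,
                 log = data.frame(SNP = variant_ids,
                                  action = rep("kept", J),
                                  stringsAsFactors = FALSE)),
            class = "harmonized_set")
}

#' Assemble a harmonized set from aligned effect vectors
#'
#' Convenience constructor for already-aligned per-variant exposure and
#' outcome effects, e.g. simulated data or effects exported by another
#' harmonization tool.
#'
#' @param beta_exposure,se_exposure Exposure effects and standard errors.
#' @param beta_outcome,se_outcome Outcome effects and standard errors
#'   (log-odds scale for binary outcomes).
#' @param variant_ids Optional variant identifiers.
#' @param exposure_name,outcome_name Trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, variant_ids = NULL,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  harmonized_from_arrays(beta_exposure, se_exposure, beta_outcome,
                         se_outcome, variant_ids, exposure_name,
                         outcome_name)
}
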