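#' AssocPanel: per-variant association statistics for one trait
#'
#' Summary statistics for a single trait over a set of variants, as used by
#' approximate Bayes factor colocalisation: per-variant effect estimates,
#' standard errors, minor allele frequencies and sample sizes, plus the lead
#' variant of the signal.
#'
#' @slot stats data.frame with columns `rsid`, `chrom`, `pos`, `beta`, `se`,
#'   `maf`, `n`, `trait_type` (`"quantitative"` or `"case_control"`).
#' @slot traitLabel Trait label.
#' @slot leadRsid rsid of the lead variant.
#' @export
setClass("AssocPanel",
         representation(stats = "data.frame", traitLabel = "character",
                        leadRsid = "character"))

setValidity("AssocPanel", function(object) {
  s <- object@stats
  msg <- character()
  need <- c("rsid", "beta", "se", "maf", "n", "trait_type")
  if (!all(need %in% names(s)))
    msg <- c(msg, paste("stats needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(s$rsid)) msg <- c(msg, "rsids must be unique")
    if (any(s$se <= 0)) msg <- c(msg, "se must be > 0")
    if (any(s$maf <= 0 | s$maf > 0.5)) msg <- c(msg, "maf must be in (0, 0.5]")
    if (!all(s$trait_type %in% c("quantitative", "case_control")))
      msg <- c(msg, "trait_type must be quantitative or case_control")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssocPanel
#'
#' @param stats data.frame of per-variant summary statistics (see
#'   [AssocPanel-class]).
#' @param traitLabel Trait label.
#' @param leadRsid Lead variant rsid; defaults to the variant with the
#'   largest |beta/se|.
#' @return An `AssocPanel`.
#' @export
assocPanel <- function(stats, traitLabel, leadRsid = NULL) {
  if (is.null(leadRsid))
    leadRsid <- stats$rsid[which.max(abs(stats$beta / stats$se))]
  new("AssocPanel", stats = as.data.frame(stats),
      traitLabel = traitLabel, leadRsid = leadRsid)
}

#' @rdname anchorFwd
#' @export
panelStats <- function(x) x@stats

#' @rdname anchorFwd
#' @export
traitLabel <- function(x) x@traitLabel

#' @rdname anchorFwd
#' @export
leadRsid <- function(x) x@leadRsid

setMethod("show", "AssocPanel", function(object) {
  cat("AssocPanel '", object@traitLabel, "': ", nrow(object@stats),
      " variants, lead ", object@leadRsid, "\n", sep = "")
})

#' Read an association summary-statistics table
#'
#' Tab-separated with header columns `rsid`, `chrom`, `pos`, `beta`, `se`,
#' `maf`, `n`, `trait_type`.
#'
#' @param path File path.
#' @param traitLabel Trait label for the panel.
#' @param leadRsid Optional lead rsid (see [assocPanel()]).
#' @return An `AssocPanel`.
#' @export
readAssocPanel <- function(path, traitLabel = basename(path),
                           leadRsid = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  assocPanel(df, traitLabel, leadRsid)
}

#' Restrict a panel to a window around the lead variant
#'
#' Keeps records within `halfWidth` bp either side of `leadPos` (default:
#' the position of the panel's lead variant; standard window 1 Mb).
#'
#' @param panel An `AssocPanel` whose stats include `pos`.
#' @param leadPos Centre position; taken from the lead variant when `NULL`.
#' @param halfWidth Window half-width in bp.
#' @return The windowed `AssocPanel`.
#' @export
windowPanel <- function(panel, leadPos = NULL, halfWidth = 1e6) {
  s <- panelStats(panel)
  if (is.null(leadPos)) {
    i <- match(leadRsid(panel), s$rsid)
    if (is.na(i)) stop("lead variant ", leadRsid(panel),
                       " absent from panel ", traitLabel(panel))
    leadPos <- s$pos[i]
  }
  keep <- abs(s$pos - leadPos) <= halfWidth
  new("AssocPanel", stats = s[keep, , drop = FALSE],
      traitLabel = panel@traitLabel, leadRsid = panel@leadRsid)
}

#' Wakefield log approximate Bayes factor
#'
#' For effect estimate `beta` with standard error `se` and a N(0,
#' `priorSd`^2) prior on the true effect: with V = se^2, W = priorSd^2,
#' r = W/(V + W) and z = beta/se, the log ABF is
#' `0.5 * log(1 - r) + 0.5 * r * z^2`.
#'
#' @param beta,se Effect estimate and standard error (vectorised; `se > 0`).
#' @param priorSd Prior standard deviation of the true effect (> 0).
#' @return Numeric vector of log ABFs.
#' @export
labf <- function(beta, se, priorSd) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(priorSd <= 0)) stop("priorSd must be > 0")
  V <- se^2
  r <- priorSd^2 / (V + priorSd^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * r * z^2
}

#' Default Wakefield prior effect SD by trait type
#'
#' 0.15 for quantitative traits, 0.2 for case-control (log-odds scale) —
#' the standard defaults of the approximate Bayes factor method.
#'
#' @param traitType `"quantitative"` or `"case_control"`.
#' @return Prior SD.
#' @export
wakefieldSd <- function(traitType) {
  ifelse(traitType == "case_control", 0.2, 0.15)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when equal within rounding
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate Bayes factor colocalisation of two association signals
#'
#' Restricts both panels to their shared rsids, computes per-variant
#' Wakefield log ABFs, and evaluates the posterior probabilities of the five
#' standard hypotheses: H0 no association in either trait; H1/H2
#' association in trait 1/2 only; H3 both associated with distinct causal
#' variants; H4 both associated sharing a single causal variant. All sums
#' are carried in log space; the H3 cross-term uses the identity
#' log(sum_{i != j} exp(L1_i + L2_j)) = logdiffexp(S1 + S2, S12).
#'
#' @param panel1,panel2 `AssocPanel`s for the two traits.
#' @param priors Numeric `c(p1, p2, p12)`: per-variant prior probabilities
#'   of association with trait 1 only, trait 2 only, and both.
#' @param priorSd1,priorSd2 Wakefield prior SDs; defaults from each panel's
#'   trait type via [wakefieldSd()].
#' @return One-row data.frame: `pp_h0`..`pp_h4`, `n_shared_snps`, `p1`,
#'   `p2`, `p12`.
#' @export
colocalise <- function(panel1, panel2,
                       priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                       priorSd1 = NULL, priorSd2 = NULL) {
  s1 <- panelStats(panel1)
  s2 <- panelStats(panel2)
  shared <- intersect(s1$rsid, s2$rsid)
  if (length(shared) == 0)
    stop("no shared rsids between panels '", traitLabel(panel1), "' and '",
         traitLabel(panel2), "'")
  s1 <- s1[match(shared, s1$rsid), , drop = FALSE]
  s2 <- s2[match(shared, s2$rsid), , drop = FALSE]
  if (is.null(priorSd1)) priorSd1 <- wakefieldSd(s1$trait_type[1])
  if (is.null(priorSd2)) priorSd2 <- wakefieldSd(s2$trait_type[1])
  L1 <- labf(s1$beta, s1$se, priorSd1)
  L2 <- labf(s2$beta, s2$se, priorSd2)
  S1 <- logsumexp(L1)
  S2 <- logsumexp(L2)
  S12 <- logsumexp(L1 + L2)
  p1 <- priors[[1]]; p2 <- priors[[2]]; p12 <- priors[[3]]
  lw <- c(h0 = 0,
          h1 = log(p1) + S1,
          h2 = log(p2) + S2,
          h3 = log(p1) + log(p2) + logdiffexp(S1 + S2, S12),
          h4 = log(p12) + S12)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  data.frame(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
             pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
             n_shared_snps = length(shared), p1 = p1, p2 = p2, p12 = p12)
}

#' Select the lead phenotype among association panels
#'
#' Returns the panel whose lead variant is most significant (smallest
#' two-sided normal p-value of beta/se, compared on |z| to avoid underflow);
#' ties break lexicographically on the trait label.
#'
#' @param panels List of `AssocPanel`s.
#' @return The selected `AssocPanel`.
#' @export
selectLeadPhenotype <- function(panels) {
  stopifnot(length(panels) >= 1)
  z <- vapply(panels, function(p) {
    s <- panelStats(p)
    i <- match(leadRsid(p), s$rsid)
    if (is.na(i)) stop("lead variant absent from panel ", traitLabel(p))
    abs(s$beta[i] / s$se[i])
  }, 0)
  labels <- vapply(panels, traitLabel, "")
  panels[[order(-z, labels)[1]]]
}
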