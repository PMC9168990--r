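# Derived glycan traits computed from relative-abundance profiles.

# Term lists of the trait formulas.  The reference behaviour follows the
# printed formulas verbatim; "extended" mode additionally counts the
# doubly-decorated sialylated species the printed lists omit.
.trait_terms <- list(
  bi_n        = c("G0N", "G0NF", "G1N", "G1NF", "G2N", "G2NF"),
  fuc_total   = c("G0F", "G0NF", "G0-NF", "G1F", "G1FS", "G1NF", "G1-NF",
                  "G2F", "G2FS", "G2NF"),
  fuc_neutral = c("G0F", "G0NF", "G0-NF", "G1F", "G1NF", "G1-NF",
                  "G2F", "G2NF"),
  fuc_sialo   = c("G1FS", "G2FS"),
  sial        = c("G1S", "G1FS", "G2FS", "G2S"),
  g0          = c("G0", "G0F", "G0N", "G0NF", "G0-NF"),
  g1          = c("G1", "G1F", "G1FS", "G1-N", "G1N", "G1NF", "G1-NF",
                  "G1NFS", "G1S"),
  g2          = c("G2", "G2F", "G2FS", "G2N", "G2NF", "G2NFS", "G2S", "G2S2")
)

.trait_terms_extended <- local({
  t <- .trait_terms
  t$bi_n <- c(t$bi_n, "G1NFS", "G2NFS")
  t$fuc_total <- c(t$fuc_total, "G1NFS", "G2NFS")
  t$fuc_sialo <- c(t$fuc_sialo, "G1NFS", "G2NFS")
  t$sial <- c(t$sial, "G1NFS", "G2NFS", "G2S2")
  t
})

#' Derived glycan traits of a profile
#'
#' Aggregate glycosylation features of a relative-abundance profile:
#' bisecting GlcNAc (`bi_n`), fucosylation of all / neutral / sialylated
#' species (`fuc_total`, `fuc_neutral`, `fuc_sialo`), sialylation
#' (`sial`), the galactosylation classes `g0`, `g1`, `g2` (which
#' partition the vocabulary, so they sum to 1), and the galactosylation
#' distribution `gal_ratio = g0 / (g1 + 2 g2)` (higher means less
#' galactosylated).
#'
#' IgG3/4 abundances are always excluded; the selected scope (IgG1 only,
#' IgG2 only, or both combined) is renormalized to sum 1 before the sums
#' are taken.
#'
#' @param profile A `glyco_profile`.
#' @param scope `"total"` (IgG1 + IgG2 combined, default), `"IgG1"` or
#'   `"IgG2"`.
#' @param extended If TRUE, also count the doubly-decorated sialylated
#'   species (G1NFS/G2NFS in `bi_n` and the fucosylation traits;
#'   G1NFS/G2NFS/G2S2 in `sial`) that the reference formulas omit.
#'   Default FALSE, so the reference formulas are the default behaviour.
#' @return A `trait_profile` list with the nine traits, a `gal_defined`
#'   flag (FALSE when `g1 + 2 g2 = 0` leaves the ratio undefined, in
#'   which case `gal_ratio` is NA), and the `scope`.
#' @export
#' @examples
#' prof <- relative_intensity(
#'   data.frame(subclass = "IgG1", glycoform = c("G0F", "G1F"),
#'              height = c(2, 3)))
#' compute_traits(prof, scope = "IgG1")
compute_traits <- function(profile, scope = c("total", "IgG1", "IgG2"),
                           extended = FALSE) {
  scope <- match.arg(scope)
  keep <- if (scope == "total") profile$subclass %in% c("IgG1", "IgG2")
          else profile$subclass == scope
  sub <- profile[keep, , drop = FALSE]
  total <- sum(sub$abundance)
  if (total <= 0)
    glyco_stop(sprintf("no abundance in scope '%s'", scope),
               "glycomig_quantification_error")
  # combined scope: sum the two subclasses per glycoform, then renormalize
  ab <- tapply(sub$abundance, sub$glycoform, sum) / total
  terms <- if (extended) .trait_terms_extended else .trait_terms
  val <- function(names) sum(ab[intersect(names, names(ab))])
  out <- lapply(terms, val)
  denom <- out$g1 + 2 * out$g2
  out$gal_defined <- denom > 0
  out$gal_ratio <- if (out$gal_defined) out$g0 / denom else NA_real_
  out$scope <- scope
  class(out) <- "trait_profile"
  out
}

#' @export
print.trait_profile <- function(x, ...) {
  cat(sprintf("<trait_profile> scope %s\n", x$scope))
  v <- unlist(x[c("bi_n", "fuc_total", "fuc_neutral", "fuc_sialo", "sial",
                  "g0", "g1", "g2", "gal_ratio")])
  print(round(v, 4))
  invisible(x)
}

#' Trait table for a cohort feature matrix
#'
#' Computes [compute_traits()] for every row of a wide sample-by-
#' glycopeptide abundance table (columns named `"<subclass> <glycoform>"`).
#'
#' @param features Data frame or matrix, rows = samples, columns =
#'   glycopeptide feature ids.
#' @param scope,extended Passed to [compute_traits()].
#' @return Data frame of the nine traits, one row per sample.
#' @export
trait_table <- function(features, scope = "total", extended = FALSE) {
  ids <- strsplit(colnames(features), " ", fixed = TRUE)
  subclass <- vapply(ids, `[[`, character(1), 1L)
  glycoform <- vapply(ids, function(x) paste(x[-1], collapse = " "), character(1))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    prof <- new_glyco_profile(subclass, glycoform, as.numeric(features[i, ]))
    tr <- compute_traits(prof, scope = scope, extended = extended)
    unlist(tr[c("bi_n", "fuc_total", "fuc_neutral", "fuc_sialo", "sial",
                "g0", "g1", "g2", "gal_ratio")])
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- rownames(features)
  out
}
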