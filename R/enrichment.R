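# Categorical enrichment statistics: Fisher's exact test over annotation
# terms and rank-based 1D annotation enrichment over numeric protein
# scores.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: q_(i) = min over j >= i of p_(j) * m / j, clipped
#' to 1 and mapped back to input order.  NA p-values propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, q >= p elementwise.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher exact enrichment of annotation terms among flagged proteins
#'
#' For each term, a 2x2 table is built over the universe: a = flagged
#' members, b = unflagged members, c = flagged non-members, d = the rest.
#' The two-sided p-value is the exact hypergeometric test (sum of point
#' probabilities not exceeding the observed one) and the enrichment
#' factor is observed/expected: a / ((a+b)(a+c)/N).  Terms with fewer
#' than `min_size` members in the universe are skipped.
#'
#' @param flags named logical vector per protein (e.g. `significant` from
#'   [differential_abundance()]).
#' @param catalog an `annotation_catalog` (named list of term vectors).
#' @param universe "annotated" restricts the universe to proteins with at
#'   least one term (the usual convention when the background annotation
#'   is incomplete); "all" uses every flagged-or-not protein.  The choice
#'   of background can shift enrichment outcomes appreciably when only a
#'   minority of the proteome is annotated.
#' @param min_size minimum term membership in the universe.
#' @return data.frame of class `enrichment_result`: term, a, b, c, d,
#'   n_term, enrichment_factor, direction, p, q; skipped terms in
#'   attribute `"skipped_terms"`.
#' @export
fisher_enrichment <- function(flags, catalog,
                              universe = c("annotated", "all"),
                              min_size = 3) {
  universe <- match.arg(universe)
  if (is.null(names(flags))) stopf("flags must be a named logical vector")
  annotated <- names(catalog)[lengths(catalog) > 0]
  uni <- if (universe == "annotated")
    intersect(names(flags), annotated) else names(flags)
  if (length(uni) == 0) stopf("empty universe: no %s proteins among the flags",
                              universe)
  fl <- flags[uni]
  fl[is.na(fl)] <- FALSE
  term_sets <- catalog[intersect(uni, names(catalog))]
  members_of <- split(rep(names(term_sets), lengths(term_sets)),
                      unlist(term_sets, use.names = FALSE))
  terms <- sort(names(members_of))
  N <- length(uni)
  n_flag <- sum(fl)

  rows <- list(); skipped <- character(0)
  for (tm in terms) {
    memb <- uni %in% members_of[[tm]]
    a <- sum(fl & memb); b <- sum(!fl & memb)
    cc <- n_flag - a; dd <- N - a - b - cc
    if (a + b < min_size) {
      skipped <- c(skipped, tm)
      next
    }
    expected <- (a + b) * (a + cc) / N
    factor <- if (expected > 0) a / expected else NA_real_
    p <- stats::fisher.test(matrix(c(a, b, cc, dd), nrow = 2))$p.value
    rows[[length(rows) + 1]] <- data.frame(
      term = tm, a = a, b = b, c = cc, d = dd, n_term = a + b,
      enrichment_factor = factor,
      direction = if (is.na(factor)) NA_character_ else
        if (factor >= 1) "enriched" else "depleted",
      p = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), n_term = integer(0),
               enrichment_factor = numeric(0), direction = character(0),
               p = numeric(0), stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  attr(out, "skipped_terms") <- skipped
  attr(out, "universe_size") <- N
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @noRd
rank_sum_test <- function(v, is_member) {
  n1 <- sum(is_member); n2 <- sum(!is_member)
  N <- n1 + n2
  rk <- rank(v)  # ascending, average ties
  U <- sum(rk[is_member]) - n1 * (n1 + 1) / 2
  s <- 2 * U / (n1 * n2) - 1
  ties <- table(v)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, s = 0, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, s = s, p = 2 * stats::pnorm(-abs(z)))
}

#' 1D annotation enrichment over ranked protein values
#'
#' Rank-based (Mann-Whitney) test per annotation term on a numeric
#' protein score, as used to ask whether a category's proteins tend to sit
#' high or low in a ranking of, say, normalized intensity per sample or
#' log2 fold change.  With proteins ranked ascending,
#' U = sum(member ranks) - n1(n1+1)/2 and the position score
#' s = 2U/(n1 n2) - 1 lies in \[-1, 1\]: +1 when members hold the top
#' ranks, -1 at the bottom, 0 when member and non-member mean ranks agree.
#' Two-sided p-values use the tie-corrected normal approximation;
#' Benjamini-Hochberg adjustment runs across terms within each sample.
#'
#' @param values named numeric vector, or a matrix/data.frame (proteins x
#'   samples, rownames = protein ids) tested one column at a time.
#' @param catalog an `annotation_catalog`.
#' @param min_members minimum members and non-members with defined values.
#' @return data.frame of class `oned_enrichment_result`: sample, term,
#'   n_members, U, s, p, q.
#' @export
one_d_annotation_enrichment <- function(values, catalog, min_members = 2) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) {
    if (is.null(names(values))) stopf("values must be named by protein id")
    values <- matrix(values, ncol = 1,
                     dimnames = list(names(values), "value"))
  }
  if (is.null(rownames(values))) stopf("values must have protein-id rownames")
  term_members <- split(rep(names(catalog), lengths(catalog)),
                        unlist(catalog, use.names = FALSE))
  terms <- sort(names(term_members))

  res <- list()
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    v <- v[!is.na(v)]
    rows <- list()
    for (tm in terms) {
      memb <- names(v) %in% term_members[[tm]]
      n1 <- sum(memb); n2 <- sum(!memb)
      if (n1 < min_members || n2 < min_members) next
      rs <- rank_sum_test(v, memb)
      rows[[length(rows) + 1]] <- data.frame(
        sample = colnames(values)[j], term = tm, n_members = n1,
        U = rs$U, s = rs$s, p = rs$p, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      block <- do.call(rbind, rows)
      block$q <- bh_adjust(block$p)
      res[[length(res) + 1]] <- block
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(sample = character(0), term = character(0),
               n_members = integer(0), U = numeric(0), s = numeric(0),
               p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("oned_enrichment_result", "data.frame")
  out
}
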