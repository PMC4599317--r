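# Genomic context of associated CpGs: region classification against gene
# models, chromatin-state assignment, long-range interaction counting, and
# Fisher enrichment of the associated set against the tested background.
#
# Internal coordinate convention: all positions and intervals are 1-based
# and inclusive (probe positions, gene spans, state tiles, anchors). The
# BED/BEDPE readers in io.R convert from 0-based half-open on the way in,
# so a BED boundary base belongs to the interval whose half-open span
# contains it.

.probes_gr <- function(probe_manifest) {
  GenomicRanges::GRanges(
    seqnames = probe_manifest$chrom,
    ranges = IRanges::IRanges(start = probe_manifest$pos, width = 1L))
}

#' Classify probes against gene models
#'
#' A probe is `promoter` if within `promoter_window` bp of any TSS (the
#' gene start on + strand, end on - strand) and in no gene body;
#' `gene_body` if inside a transcript span only; `ambiguous` if both;
#' `intergenic` otherwise.
#'
#' @param probe_manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive spans), e.g. from [read_bed6()].
#' @param promoter_window bp around the TSS counted as promoter.
#' @return data.frame with `probe_id` and `class`.
#' @export
classify_region <- function(probe_manifest, genes, promoter_window = 1500) {
  if (!"strand" %in% names(genes) || any(!genes$strand %in% c("+", "-")))
    stop("gene models must carry strand (+ or -)")
  pr <- .probes_gr(probe_manifest)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, tss - promoter_window),
                              end = tss + promoter_window))
  body <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  in_prom <- IRanges::overlapsAny(pr, prom)
  in_body <- IRanges::overlapsAny(pr, body)
  cls <- ifelse(in_prom & in_body, "ambiguous",
                ifelse(in_prom, "promoter",
                       ifelse(in_body, "gene_body", "intergenic")))
  data.frame(probe_id = probe_manifest$probe_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Assign chromatin-state categories to probes
#'
#' Looks up, per tissue, the segmentation interval containing each probe
#' position and returns its collapsed category. State labels are mapped to
#' the seven categories through `state_to_category`; segmentations already
#' carrying a `category` column need no map. Positions not covered by the
#' tiling get category `NA` with status `"uncovered"`.
#'
#' @param probe_manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param segmentations named list (per tissue) of data.frames with
#'   `chrom`, `start`, `end` and either `category` or `state`
#'   (1-based inclusive intervals).
#' @param state_to_category named character vector mapping state labels to
#'   the seven categories; required when segmentations carry `state`.
#' @return data.frame with `probe_id`, `tissue`, `category`, `status`.
#' @export
assign_state <- function(probe_manifest, segmentations,
                         state_to_category = NULL) {
  pr <- .probes_gr(probe_manifest)
  out <- list()
  for (tissue in names(segmentations)) {
    seg <- segmentations[[tissue]]
    if ("category" %in% names(seg)) {
      cat_col <- seg$category
    } else if ("state" %in% names(seg)) {
      if (is.null(state_to_category))
        stop("state_to_category map required for state-labelled segmentations")
      unmapped <- setdiff(unique(seg$state), names(state_to_category))
      if (length(unmapped))
        stop("unmapped state labels: ", paste(unmapped, collapse = ", "))
      cat_col <- unname(state_to_category[seg$state])
    } else stop("segmentation needs a 'category' or 'state' column")
    bad <- !cat_col %in% STATE_CATEGORIES
    if (any(bad))
      stop("unknown categories: ", paste(unique(cat_col[bad]), collapse = ", "))
    gr <- GenomicRanges::GRanges(
      seqnames = seg$chrom,
      ranges = IRanges::IRanges(start = seg$start, end = seg$end))
    hit <- GenomicRanges::findOverlaps(pr, gr, select = "first")
    out[[tissue]] <- data.frame(
      probe_id = probe_manifest$probe_id, tissue = tissue,
      category = ifelse(is.na(hit), NA_character_, cat_col[hit]),
      status = ifelse(is.na(hit), "uncovered", "assigned"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count long-range interactions overlapping each probe
#'
#' For every probe, counts the anchor pairs with either anchor containing
#' the probe position. If gene models are supplied, also flags whether any
#' such pair has its partner anchor overlapping a gene promoter
#' (TSS +/- `promoter_window`).
#'
#' @param probe_manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param anchors BEDPE-style data.frame with `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2` (1-based inclusive), e.g. from
#'   [read_bedpe()].
#' @param genes optional gene models for the promoter flag.
#' @param promoter_window bp around the TSS.
#' @return data.frame with `probe_id`, `n_interactions`,
#'   `promoter_interaction`.
#' @export
count_interactions <- function(probe_manifest, anchors, genes = NULL,
                               promoter_window = 1500) {
  if (nrow(anchors)) {
    if (any(anchors$end1 < anchors$start1 | anchors$end2 < anchors$start2))
      stop("malformed anchor pair (end < start) at row ",
           which(anchors$end1 < anchors$start1 |
                   anchors$end2 < anchors$start2)[1])
  }
  pr <- .probes_gr(probe_manifest)
  mk <- function(chrom, s, e) GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = s, end = e))
  if (nrow(anchors) == 0) {
    return(data.frame(probe_id = probe_manifest$probe_id,
                      n_interactions = 0L,
                      promoter_interaction = FALSE,
                      stringsAsFactors = FALSE))
  }
  a1 <- mk(anchors$chrom1, anchors$start1, anchors$end1)
  a2 <- mk(anchors$chrom2, anchors$start2, anchors$end2)
  h1 <- GenomicRanges::findOverlaps(pr, a1)
  h2 <- GenomicRanges::findOverlaps(pr, a2)
  n <- tabulate(c(S4Vectors::queryHits(h1), S4Vectors::queryHits(h2)),
                nbins = length(pr))
  prom_flag <- rep(FALSE, length(pr))
  if (!is.null(genes)) {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    prom <- mk(genes$chrom, pmax(1L, tss - promoter_window),
               tss + promoter_window)
    partner_prom1 <- IRanges::overlapsAny(a2, prom)  # probe in a1
    partner_prom2 <- IRanges::overlapsAny(a1, prom)  # probe in a2
    for (h in list(list(h1, partner_prom1), list(h2, partner_prom2))) {
      q <- S4Vectors::queryHits(h[[1]]); s <- S4Vectors::subjectHits(h[[1]])
      hitp <- h[[2]][s]
      if (any(hitp)) prom_flag[unique(q[hitp])] <- TRUE
    }
  }
  data.frame(probe_id = probe_manifest$probe_id, n_interactions = n,
             promoter_interaction = prom_flag, stringsAsFactors = FALSE)
}

#' Fisher enrichment of the associated set against the tested background
#'
#' For each category, builds the 2x2 table of category membership among
#' associated probes versus the background and tests it with Fisher's
#' exact test (two-sided: the sum of all table probabilities no larger
#' than the observed table's). The background is, by default, the tested
#' probes that are not associated, so the two groups are disjoint as the
#' test requires; `background = "all_tested"` reproduces the overlapping
#' associated-versus-all-tested comparison instead. Q-values are computed
#' across the categories supplied together (one family).
#'
#' @param associated character vector of associated probe ids (subset of
#'   `tested`, nonempty).
#' @param tested character vector of all tested probe ids.
#' @param membership logical matrix or data.frame, probes x categories
#'   (rownames are probe ids), or a named logical vector for a single
#'   category.
#' @param background `"disjoint"` (default) or `"all_tested"`.
#' @return data.frame with one row per category: `category`, `n_assoc_in`,
#'   `n_assoc_out`, `n_bg_in`, `n_bg_out`, `odds_ratio` (ad/bc),
#'   `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(associated, tested, membership,
                              background = c("disjoint", "all_tested")) {
  background <- match.arg(background)
  if (length(associated) == 0) stop("associated set is empty")
  if (!all(associated %in% tested))
    stop("associated must be a subset of tested")
  if (is.vector(membership) && !is.list(membership))
    membership <- matrix(membership, ncol = 1,
                         dimnames = list(names(membership), "category"))
  membership <- as.matrix(membership)
  if (!all(tested %in% rownames(membership)))
    stop("membership missing for some tested probes")
  bg <- if (background == "disjoint") setdiff(tested, associated) else tested
  rows <- lapply(colnames(membership), function(cat) {
    inset <- membership[, cat]
    a <- sum(inset[associated]); b <- length(associated) - a
    c_ <- sum(inset[bg]); d <- length(bg) - c_
    # fisher.test can exceed 1 by rounding; clamp to the probability scale
    p <- min(1, fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value)
    or <- (a * d) / (b * c_)
    data.frame(category = cat, n_assoc_in = a, n_assoc_out = b,
               n_bg_in = c_, n_bg_out = d, odds_ratio = or,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- storey_qvalues(res$p_value)$q_values
  rownames(res) <- NULL
  res
}

#' Compare interaction counts between associated and background probes
#'
#' Two-sided Mann-Whitney U test with tie correction for the null that the
#' per-probe interaction-count distributions are equal; counts are heavily
#' skewed, so a rank test is used rather than a t test. For combined
#' sample sizes of 12 or fewer, an exact permutation p-value (complete
#' enumeration of group labelings) replaces the normal approximation.
#'
#' @param counts_associated,counts_background nonempty integer vectors of
#'   per-probe interaction counts.
#' @param exact_max combined size at or below which the exact permutation
#'   distribution is used.
#' @return list with `u` (U statistic of the first group), `p_value`,
#'   `method`.
#' @export
compare_interaction_counts <- function(counts_associated,
                                       counts_background,
                                       exact_max = 12) {
  x <- as.numeric(counts_associated); y <- as.numeric(counts_background)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  u_of <- function(rx, nx, ny) sum(rx) - nx * (nx + 1) / 2
  u <- u_of(r[seq_len(n1)], n1, n2)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_of(r[i], n1, n2))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    # normal approximation with tie correction
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p_value = 1, method = "degenerate"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(u = u, p_value = min(p, 1), method = method)
}

#' Annotate probes against all context layers
#'
#' Combines [classify_region()], [assign_state()], [count_interactions()],
#' and enhancer membership into one probe-level annotation table.
#'
#' @param probe_manifest data.frame with `probe_id`, `chrom`, `pos`.
#' @param genes gene models (see [classify_region()]).
#' @param states named list of segmentations (see [assign_state()]).
#' @param interactions BEDPE-style anchors (see [count_interactions()]).
#' @param enhancers optional data.frame of enhancer intervals
#'   (`chrom`, `start`, `end`, 1-based inclusive).
#' @param state_to_category optional state label map.
#' @param promoter_window bp around the TSS.
#' @return data.frame, one row per probe: region class, one
#'   `state_<tissue>` column per tissue, `n_interactions`,
#'   `promoter_interaction`, `in_enhancer`.
#' @export
annotate_probes <- function(probe_manifest, genes, states = NULL,
                            interactions = NULL, enhancers = NULL,
                            state_to_category = NULL,
                            promoter_window = 1500) {
  ann <- classify_region(probe_manifest, genes, promoter_window)
  if (!is.null(states)) {
    st <- assign_state(probe_manifest, states, state_to_category)
    for (tissue in unique(st$tissue)) {
      v <- st[st$tissue == tissue, ]
      ann[[paste0("state_", tissue)]] <-
        v$category[match(ann$probe_id, v$probe_id)]
    }
  }
  if (!is.null(interactions)) {
    ic <- count_interactions(probe_manifest, interactions, genes,
                             promoter_window)
    ann$n_interactions <- ic$n_interactions
    ann$promoter_interaction <- ic$promoter_interaction
  }
  if (!is.null(enhancers)) {
    pr <- .probes_gr(probe_manifest)
    egr <- GenomicRanges::GRanges(
      seqnames = enhancers$chrom,
      ranges = IRanges::IRanges(start = enhancers$start,
                                end = enhancers$end))
    ann$in_enhancer <- IRanges::overlapsAny(pr, egr)
  }
  ann
}
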