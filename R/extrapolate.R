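## Step-wise locus-linkage breakdown: enumerate all high-resolution
## genotypes consistent with a (possibly serological) phenotype, with
## frequencies from a haplotype table, falling back through five linkage
## schemes when tighter schemes yield no candidate.

#' The five locus-linkage schemes
#'
#' Candidate haplotypes are built from linked blocks of loci. When the
#' full five-locus table contains no haplotype compatible with the input,
#' the linkage between loci is broken step-wise, in this fixed order:
#' \enumerate{
#'   \item A-B-C-DRB1-DQB1 (full haplotypes)
#'   \item A-B-C | DRB1-DQB1
#'   \item A | B-C | DRB1-DQB1
#'   \item A | B-C | DRB1 | DQB1
#'   \item A | B | C | DRB1 | DQB1 (per-locus allele frequencies)
#' }
#'
#' @return A list of five schemes; each scheme is a list of character
#'   vectors (the linked blocks).
#' @export
linkage_schemes <- function() {
  list(
    list(c("A", "B", "C", "DRB1", "DQB1")),
    list(c("A", "B", "C"), c("DRB1", "DQB1")),
    list("A", c("B", "C"), c("DRB1", "DQB1")),
    list("A", c("B", "C"), "DRB1", "DQB1"),
    list("A", "B", "C", "DRB1", "DQB1")
  )
}

#' Human-readable label for a linkage scheme
#' @param scheme Scheme index 1-5.
#' @return A string such as `"A|B-C|DRB1-DQB1"`.
#' @export
scheme_label <- function(scheme) {
  vapply(scheme, function(s) {
    blocks <- linkage_schemes()[[s]]
    paste(vapply(blocks, paste, character(1L), collapse = "-"),
          collapse = "|")
  }, character(1L))
}

#' Marginal frequencies of a locus block
#'
#' The marginal frequency of a partial haplotype (the alleles at one
#' linked block of loci) is the sum of table frequencies over all full
#' haplotypes that agree with it at the block's loci.
#'
#' @param table An `hla_freq_table`.
#' @param block Character vector of loci forming the block.
#' @return Data frame with one column per block locus plus `freq`.
#' @export
block_marginals <- function(table, block) {
  df <- as.data.frame(table)
  key <- do.call(paste, c(df[block], sep = "|"))
  agg <- rowsum(df$freq, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "|", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- block
  out$freq <- as.numeric(agg[, 1L])
  rownames(out) <- NULL
  out
}

## Integer match mask for alleles at one locus against the phenotype's
## 1-2 values there: bit 1 set if the allele projects to values[1], bit 2
## if it projects to values[2]. Projection is at each value's own level
## (two-field equality for allele values, serological identity otherwise).
.locus_match_mask <- function(alleles, values, map) {
  ua <- unique(alleles)
  mask <- integer(length(ua))
  for (k in seq_along(values)) {
    v <- values[[k]]
    hit <- if (is_allele_value(v)) {
      ua == v
    } else {
      lvl <- value_level(v, map)
      serologize(ua, map, lvl) == v
    }
    mask <- mask + as.integer(hit) * (2L^(k - 1L))
  }
  mask[match(alleles, ua)]
}

#' Test a haplotype (or block) against a phenotype
#'
#' The pair-compatibility primitive behind candidate enumeration: TRUE iff
#' at every phenotype locus covered by `alleles`, the allele projects (by
#' serology, or two-field equality for allele-valued phenotypes) to one of
#' the phenotype's values. Loci absent from the phenotype are
#' unconstrained. Note that a single haplotype matching is necessary but
#' not sufficient for a genotype: the *pair* must jointly reproduce the
#' phenotype (see [enumerate_candidates()]).
#'
#' @param alleles Named character vector of alleles (a haplotype or a
#'   block of one).
#' @param phenotype An `hla_phenotype`.
#' @param map An `hla_serology_map`.
#' @return Logical scalar.
#' @export
matches <- function(alleles, phenotype, map) {
  alleles <- stats::setNames(normalize_allele(unname(alleles), NULL),
                             names(alleles))
  for (loc in intersect(names(phenotype), names(alleles))) {
    m <- .locus_match_mask(alleles[[loc]], phenotype[[loc]], map)
    if (m == 0L) return(FALSE)
  }
  TRUE
}

#' Enumerate candidate high-resolution genotypes under one linkage scheme
#'
#' Builds every unordered pair of five-locus allele vectors constructible
#' from the scheme's block marginals whose joint projection reproduces the
#' phenotype exactly at every covered locus: each phenotype value is hit
#' by at least one haplotype of the pair and neither haplotype projects
#' outside the phenotype's values. Under the full-haplotype scheme the
#' pair frequency is the product of the two haplotype frequencies; under
#' broken linkage each chromosome's frequency is the product of its
#' blocks' marginal frequencies, and all cross-block phase assignments are
#' distinct enumerated chromosomes (duplicate unordered genotypes cannot
#' arise because partial combinations map injectively to allele vectors).
#'
#' @param phenotype An `hla_phenotype` (nonempty).
#' @param table An `hla_freq_table`.
#' @param map An `hla_serology_map`.
#' @param scheme Scheme index 1-5 (see [linkage_schemes()]).
#' @param hw_factor If TRUE, heterozygous pairs get the Hardy-Weinberg
#'   factor 2. The default is the literal product of the two frequencies,
#'   with no factor.
#' @param single_as_unknown If TRUE, a single value at a locus is read as
#'   "second value unknown" instead of the default "homozygous at the
#'   typed resolution".
#' @param max_candidates Hard cap on enumerated genotype pairs; broken
#'   linkage on rich tables is combinatorial.
#' @return A data.frame of class `hla_candidates` with columns
#'   `h1_A..h1_DQB1`, `h2_A..h2_DQB1`, `freq`, pairs canonically ordered
#'   and deduplicated; zero rows when nothing matches (which triggers the
#'   fallback in [extrapolate()]).
#' @export
enumerate_candidates <- function(phenotype, table, map, scheme = 1L,
                                 hw_factor = FALSE,
                                 single_as_unknown = FALSE,
                                 max_candidates = 1e6) {
  stopifnot(inherits(phenotype, "hla_phenotype"))
  if (length(phenotype) == 0L) stop("phenotype is empty", call. = FALSE)
  blocks <- linkage_schemes()[[scheme]]

  ## per block: marginal partials, filtered for per-chromosome
  ## compatibility with the phenotype at covered loci
  block_parts <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    marg <- block_marginals(table, bl)
    keep <- rep(TRUE, nrow(marg))
    for (loc in intersect(bl, names(phenotype))) {
      vals <- phenotype[[loc]]
      m <- .locus_match_mask(marg[[loc]], vals, map)
      if (length(vals) == 1L && single_as_unknown) next  # pair-level only
      keep <- keep & (m > 0L)
    }
    marg <- marg[keep, , drop = FALSE]
    if (nrow(marg) == 0L) return(.empty_candidates(scheme))
    block_parts[[b]] <- marg
  }

  ## chromosomes = cross product of block partials
  n_chrom <- prod(vapply(block_parts, nrow, integer(1L)))
  if (n_chrom * (n_chrom + 1) / 2 > max_candidates) {
    stop(sprintf(
      "candidate explosion: %d chromosomes imply > %g genotype pairs (cap %g)",
      n_chrom, n_chrom * (n_chrom + 1) / 2, max_candidates), call. = FALSE)
  }
  idx <- expand.grid(lapply(block_parts, function(p) seq_len(nrow(p))),
                     KEEP.OUT.ATTRS = FALSE)
  chrom <- matrix(NA_character_, nrow = n_chrom, ncol = 5L,
                  dimnames = list(NULL, HLA_LOCI))
  cfreq <- rep(1, n_chrom)
  for (b in seq_along(blocks)) {
    part <- block_parts[[b]][idx[[b]], , drop = FALSE]
    for (loc in blocks[[b]]) chrom[, loc] <- part[[loc]]
    cfreq <- cfreq * part$freq
  }

  ## per-chromosome match masks at covered loci; a pair is a candidate iff
  ## the OR of its masks equals the full mask at every covered locus
  cov <- names(phenotype)
  full <- vapply(cov, function(loc) {
    if (length(phenotype[[loc]]) == 2L) 3L else 1L
  }, integer(1L))
  M <- matrix(0L, nrow = n_chrom, ncol = length(cov),
              dimnames = list(NULL, cov))
  for (loc in cov) {
    M[, loc] <- .locus_match_mask(chrom[, loc], phenotype[[loc]], map)
  }

  i_out <- integer(0); j_out <- integer(0)
  for (i in seq_len(n_chrom)) {
    j <- i:n_chrom
    ok <- rep(TRUE, length(j))
    for (l in seq_along(cov)) {
      ok <- ok & (bitwOr(M[i, l], M[j, l]) == full[[l]])
    }
    jj <- j[ok]
    i_out <- c(i_out, rep.int(i, length(jj)))
    j_out <- c(j_out, jj)
  }
  if (length(i_out) == 0L) return(.empty_candidates(scheme))

  freq <- cfreq[i_out] * cfreq[j_out]
  if (hw_factor) freq <- freq * ifelse(i_out == j_out, 1, 2)

  h1 <- chrom[i_out, , drop = FALSE]
  h2 <- chrom[j_out, , drop = FALSE]
  ## canonical order within the unordered pair
  k1 <- apply(h1, 1L, paste, collapse = "|")
  k2 <- apply(h2, 1L, paste, collapse = "|")
  swap <- k1 > k2
  if (any(swap)) {
    tmp <- h1[swap, , drop = FALSE]
    h1[swap, ] <- h2[swap, , drop = FALSE]
    h2[swap, ] <- tmp
  }
  out <- data.frame(h1, h2, freq, stringsAsFactors = FALSE)
  names(out) <- c(paste0("h1_", HLA_LOCI), paste0("h2_", HLA_LOCI), "freq")
  rownames(out) <- NULL
  structure(out, class = c("hla_candidates", "data.frame"), scheme = scheme)
}

.empty_candidates <- function(scheme) {
  out <- data.frame(matrix(character(0), 0L, 10L), freq = numeric(0),
                    stringsAsFactors = FALSE)
  names(out) <- c(paste0("h1_", HLA_LOCI), paste0("h2_", HLA_LOCI), "freq")
  structure(out, class = c("hla_candidates", "data.frame"), scheme = scheme)
}

#' Impute high-resolution genotypes from a phenotype
#'
#' Runs [enumerate_candidates()] under the full-haplotype scheme first,
#' and on an empty result falls back through the remaining linkage
#' schemes in order, stopping at the first scheme with at least one
#' candidate. Frequencies are then normalized to weights summing to 1
#' within the candidate set (the multiple-imputation weights). If even
#' the per-locus scheme yields nothing — some input value has no mapped
#' allele anywhere in the table — the phenotype is unimputable and a
#' typed result records that, mirroring the small fraction of real
#' couples for which no estimate can be produced.
#'
#' @inheritParams enumerate_candidates
#' @return An object of class `hla_imputation`: a list with `candidates`
#'   (an `hla_candidates` data.frame with a `weight` column), `scheme`
#'   (index used), `n_candidates` and `unimputable = FALSE`; or, on total
#'   failure, a list with `unimputable = TRUE` (classes
#'   `hla_unimputable`, `hla_imputation`).
#' @export
extrapolate <- function(phenotype, table, map, hw_factor = FALSE,
                        single_as_unknown = FALSE, max_candidates = 1e6) {
  for (s in seq_along(linkage_schemes())) {
    cand <- enumerate_candidates(phenotype, table, map, scheme = s,
                                 hw_factor = hw_factor,
                                 single_as_unknown = single_as_unknown,
                                 max_candidates = max_candidates)
    if (nrow(cand) > 0L) {
      cand$weight <- cand$freq / sum(cand$freq)
      return(structure(
        list(candidates = cand, scheme = s,
             scheme_label = scheme_label(s),
             n_candidates = nrow(cand), unimputable = FALSE),
        class = "hla_imputation"))
    }
  }
  structure(
    list(candidates = NULL, scheme = NA_integer_, scheme_label = NA_character_,
         n_candidates = 0L, unimputable = TRUE, phenotype = phenotype),
    class = c("hla_unimputable", "hla_imputation"))
}

#' @export
print.hla_imputation <- function(x, ...) {
  if (isTRUE(x$unimputable)) {
    cat("<hla_imputation> unimputable: no candidate under any linkage scheme\n")
  } else {
    cat(sprintf("<hla_imputation> %d candidate genotype(s), scheme [%s] %s\n",
                x$n_candidates, c("i", "ii", "iii", "iv", "v")[x$scheme],
                x$scheme_label))
  }
  invisible(x)
}

## Extract candidate i of an imputation/candidate frame as an hla_genotype.
#' Extract one candidate genotype
#' @param candidates An `hla_candidates` data.frame (or `hla_imputation`).
#' @param i Row index.
#' @return An `hla_genotype`.
#' @export
candidate_genotype <- function(candidates, i) {
  if (inherits(candidates, "hla_imputation")) candidates <- candidates$candidates
  h1 <- stats::setNames(unlist(candidates[i, paste0("h1_", HLA_LOCI)],
                               use.names = FALSE), HLA_LOCI)
  h2 <- stats::setNames(unlist(candidates[i, paste0("h2_", HLA_LOCI)],
                               use.names = FALSE), HLA_LOCI)
  hla_genotype(h1, h2)
}
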