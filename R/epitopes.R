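## Epitope engines: HLAMatchmaker-style eplet mismatch counting and a
## PIRCHE-II pipeline (peptide scanning, DRB1 binding filter at IC50 <
## 1000 nM, nonamer self-core exclusion) behind a pluggable binding
## predictor.

#' Construct an epitope score
#' @param items Character vector of eplet names or 9-mer cores.
#' @param engine `"eplet"` or `"pirche2"`.
#' @param count Integer count; defaults to `length(items)` and must equal
#'   it when the items are globally deduplicated.
#' @return Object of class `epitope_score`.
#' @export
epitope_score <- function(items, engine, count = length(items)) {
  structure(list(count = as.integer(count), items = items, engine = engine),
            class = "epitope_score")
}

#' @export
print.epitope_score <- function(x, ...) {
  cat(sprintf("<epitope_score> %s = %d\n", x$engine, x$count))
  invisible(x)
}

#' Count mismatched eplets between donor and recipient
#'
#' A mismatched eplet is an eplet present on any donor HLA molecule and
#' absent from every recipient HLA molecule. Comparison is interlocus:
#' by default eplets from all five loci are pooled on both sides, so an
#' eplet carried by a recipient allele at any locus neutralizes it. The
#' `per_class` option restricts pooling to within class I (A, B, C) and
#' class II (DRB1, DQB1) separately, a variant seen in HLAMatchmaker
#' practice.
#'
#' @param donor,recipient Genotypes (`hla_genotype` or character vectors
#'   of allele names).
#' @param registry Named list mapping allele -> character vector of eplet
#'   names (see [read_eplet_registry()]).
#' @param per_class If TRUE, pool eplets within class I and class II
#'   separately instead of across all five loci.
#' @return An `epitope_score` whose `items` are the mismatched eplets.
#' @export
count_eplet_mismatches <- function(donor, recipient, registry,
                                   per_class = FALSE) {
  d_alleles <- unique(genotype_alleles(donor))
  r_alleles <- unique(genotype_alleles(recipient))
  .check_registry(registry, c(d_alleles, r_alleles))
  if (!per_class) {
    items <- setdiff(.eplet_union(d_alleles, registry),
                     .eplet_union(r_alleles, registry))
  } else {
    class1 <- c("A", "B", "C")
    d1 <- d_alleles[allele_locus(d_alleles) %in% class1]
    d2 <- setdiff(d_alleles, d1)
    r1 <- r_alleles[allele_locus(r_alleles) %in% class1]
    r2 <- setdiff(r_alleles, r1)
    items <- union(
      setdiff(.eplet_union(d1, registry), .eplet_union(r1, registry)),
      setdiff(.eplet_union(d2, registry), .eplet_union(r2, registry)))
  }
  epitope_score(sort(items), "eplet")
}

.eplet_union <- function(alleles, registry) {
  unique(unlist(registry[alleles], use.names = FALSE))
}

.check_registry <- function(registry, alleles) {
  missing <- setdiff(alleles, names(registry))
  if (length(missing)) {
    stop(sprintf("allele(s) not annotated in eplet registry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Sliding peptide windows over a protein sequence
#'
#' All contiguous windows of the given length, step 1, in order. A
#' sequence shorter than the window yields the whole sequence once (it
#' can still carry a nonamer core).
#'
#' @param sequence Amino-acid string.
#' @param window Window length, at least 9 (class-II peptides are
#'   conventionally 15-mers).
#' @return Character vector of peptides.
#' @export
generate_peptides <- function(sequence, window = 15L) {
  window <- as.integer(window)
  if (window < 9L) stop("peptide window must be >= 9", call. = FALSE)
  n <- nchar(sequence)
  if (n <= window) return(sequence)
  starts <- seq_len(n - window + 1L)
  substring(sequence, starts, starts + window - 1L)
}

## Deterministic polynomial string hash into [0, 2^31-2]; the mock
## predictor's only source of "randomness", fixed for reproducibility.
.fixed_hash <- function(s) {
  p <- 2147483647
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% p
  h
}

## a*b mod p for a,b < 2^31, avoiding double-precision overflow by
## splitting b into 15-bit halves.
.modmul <- function(a, b, p) {
  b1 <- b %/% 32768
  b0 <- b %% 32768
  (((a * b1) %% p) * 32768 + a * b0) %% p
}

## Hashes of all 9-mer windows of a peptide concatenated with "|" and the
## allele name, computed by extending each window hash with the shared
## suffix. Vectorized over windows.
.window_hashes <- function(peptide, allele) {
  p <- 2147483647
  codes <- utf8ToInt(peptide)
  n <- length(codes) - 8L
  h <- numeric(n)
  idx <- seq_len(n)
  for (k in 0:8) h <- (h * 31 + codes[idx + k]) %% p
  suffix <- paste0("|", allele)
  hs <- .fixed_hash(suffix)
  mult <- 1
  for (k in seq_len(nchar(suffix))) mult <- (mult * 31) %% p
  (.modmul(h, mult, p) + hs) %% p
}

#' Deterministic mock class-II binding predictor
#'
#' A seed-free stand-in for an MHC class-II binding predictor, used as
#' the default test-time predictor. The 9-mer core is the window of the
#' peptide minimizing a fixed string hash of (window, DRB1 allele); the
#' IC50 is a log-uniform transform of that hash into (1, 50000) nM, so
#' any reasonably sized peptide set contains both binders (< 1000 nM) and
#' non-binders, reproducibly. A real predictor (e.g. a NetMHCIIpan
#' adapter, see [adapter_predictor()]) plugs in through the same
#' contract: `function(peptide, drb1_allele) -> binding prediction`.
#'
#' @param peptide Peptide string, length >= 9.
#' @param drb1_allele DRB1 allele name providing binding context.
#' @return A list of class `binding_prediction` with fields `peptide`,
#'   `core` (9-mer substring of `peptide`) and `ic50` (nM).
#' @export
mock_predictor <- function(peptide, drb1_allele) {
  if (nchar(peptide) < 9L) {
    stop("peptide must be at least 9 residues", call. = FALSE)
  }
  hs <- .window_hashes(peptide, drb1_allele)
  best <- which.min(hs)
  core <- substr(peptide, best, best + 8L)
  ## the affinity hash is salted so it is decorrelated from the
  ## min-selection above; otherwise nearly every peptide would bind
  u <- (.fixed_hash(paste0("ic50|", core, "|", drb1_allele)) + 0.5) / 2147483647
  structure(
    list(peptide = peptide, core = core, ic50 = exp(u * log(50000))),
    class = "binding_prediction")
}

#' Build a binding predictor from an external command
#'
#' Wraps an external class-II binding predictor (such as NetMHCIIpan)
#' invoked per (peptide, allele) through a command template. The command
#' receives the peptide and allele as arguments `{peptide}` `{allele}`
#' and must print a TSV line `peptide<TAB>allele<TAB>core<TAB>ic50`.
#' Intended for production use outside the test suite; the deterministic
#' [mock_predictor()] is the default everywhere in this package.
#'
#' @param command Command template string containing `{peptide}` and
#'   `{allele}` placeholders.
#' @return A predictor function with the standard contract.
#' @export
adapter_predictor <- function(command) {
  force(command)
  function(peptide, drb1_allele) {
    cmd <- gsub("{allele}", drb1_allele,
                gsub("{peptide}", peptide, command, fixed = TRUE),
                fixed = TRUE)
    out <- system(cmd, intern = TRUE)
    f <- strsplit(out[[length(out)]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L) stop("predictor adapter: malformed output", call. = FALSE)
    structure(list(peptide = f[[1L]], core = f[[3L]],
                   ic50 = as.numeric(f[[4L]])),
              class = "binding_prediction")
  }
}

#' Count PIRCHE-II for a donor-recipient genotype pair
#'
#' Predicted Indirectly ReCognizable HLA Epitopes presented by HLA-DRB1:
#' nonameric binding cores of peptides derived from mismatched donor HLA
#' proteins that bind recipient HLA-DRB1 and are absent from the
#' recipient's own HLA protein sequences. The pipeline:
#' \enumerate{
#'   \item mismatched donor alleles = donor alleles (any locus) not in
#'     the recipient's allele list at two-field identity;
#'   \item peptides are scanned from each mismatched allele's protein;
#'   \item each peptide is scored against each recipient DRB1 allele by
#'     the predictor;
#'   \item predictions with IC50 strictly below the threshold are kept
#'     as relevant DRB1 binders;
#'   \item a binder is discarded when its 9-mer core occurs within any
#'     recipient allele protein at any locus (the self filter);
#'   \item surviving cores are deduplicated into the PIRCHE-II set.
#' }
#'
#' @param donor,recipient Genotypes (`hla_genotype` or character vectors
#'   of allele names); the recipient must carry 1-2 DRB1 alleles.
#' @param proteins Named character vector allele -> protein sequence,
#'   covering every donor and recipient allele.
#' @param predictor Binding predictor with the
#'   `function(peptide, drb1_allele)` contract; default [mock_predictor()].
#' @param ic50_threshold Binder cutoff in nM; predictions with IC50
#'   strictly below it are kept. Default 1000.
#' @param window Peptide window length (default 15-mers, step 1).
#' @param count_per_drb1 If TRUE, count unique cores per recipient DRB1
#'   allele and sum, instead of the default global deduplication (one
#'   unique core = one PIRCHE-II).
#' @return An `epitope_score` whose `items` are the surviving cores.
#' @export
count_pirche2 <- function(donor, recipient, proteins,
                          predictor = mock_predictor,
                          ic50_threshold = 1000, window = 15L,
                          count_per_drb1 = FALSE) {
  d_alleles <- unique(genotype_alleles(donor))
  r_alleles <- unique(genotype_alleles(recipient))
  drb1 <- r_alleles[allele_locus(r_alleles) == "DRB1"]
  if (length(drb1) == 0L) {
    stop("recipient carries no DRB1 allele", call. = FALSE)
  }
  need <- unique(c(d_alleles, r_alleles))
  missing <- setdiff(need, names(proteins))
  if (length(missing)) {
    stop(sprintf("no protein sequence for allele(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  mismatched <- setdiff(d_alleles, r_alleles)
  self_seqs <- proteins[r_alleles]

  per_drb1 <- stats::setNames(
    replicate(length(drb1), character(0), simplify = FALSE), drb1)
  for (al in mismatched) {
    peptides <- generate_peptides(proteins[[al]], window)
    for (dr in drb1) {
      for (pep in peptides) {
        pred <- predictor(pep, dr)
        if (pred$ic50 >= ic50_threshold) next
        if (any(grepl(pred$core, self_seqs, fixed = TRUE))) next
        per_drb1[[dr]] <- c(per_drb1[[dr]], pred$core)
      }
    }
  }
  items <- sort(unique(unlist(per_drb1, use.names = FALSE)))
  count <- if (count_per_drb1) {
    sum(vapply(per_drb1, function(x) length(unique(x)), integer(1L)))
  } else {
    length(items)
  }
  epitope_score(items, "pirche2", count = count)
}
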