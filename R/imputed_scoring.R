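## Frequency-weighted epitope values: combine genotype imputation with an
## epitope engine into the expected score over all candidate genotype
## pairs of a donor-recipient couple.

.unimputable_error <- function(side, phenotype) {
  structure(
    class = c("epimatch_unimputable", "error", "condition"),
    list(message = sprintf(
           "%s phenotype is unimputable: no candidate genotype under any linkage scheme",
           side),
         call = NULL, side = side, phenotype = phenotype))
}

#' Is a condition (or result) an unimputable marker?
#' @param x An object.
#' @return Logical scalar.
#' @export
is_unimputable <- function(x) {
  inherits(x, "epimatch_unimputable") || inherits(x, "hla_unimputable")
}

#' Create a score cache
#'
#' Engine scores are memoized on the (donor genotype, recipient genotype,
#' engine, settings) key: candidate cross-products repeat genotype pairs
#' heavily across couples. Identical inputs always give identical
#' outputs; pass the same cache to repeated calls to share work.
#'
#' @return An environment usable as the `cache` argument of
#'   [imputed_epitope_value()].
#' @export
new_score_cache <- function() new.env(parent = emptyenv())

## Integer engine score for one resolved genotype pair, memoized.
.engine_score <- function(d_alleles, r_alleles, engine, resources, cache,
                          settings_key) {
  key <- paste(paste(sort(d_alleles), collapse = ","),
               paste(sort(r_alleles), collapse = ","),
               engine, settings_key, sep = ";")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  score <- if (engine == "eplet") {
    count_eplet_mismatches(d_alleles, r_alleles, resources$registry,
                           per_class = isTRUE(resources$per_class))$count
  } else {
    count_pirche2(
      d_alleles, r_alleles, resources$proteins,
      predictor = if (is.null(resources$predictor)) mock_predictor
                  else resources$predictor,
      ic50_threshold = if (is.null(resources$ic50_threshold)) 1000
                       else resources$ic50_threshold,
      window = if (is.null(resources$window)) 15L else resources$window,
      count_per_drb1 = isTRUE(resources$count_per_drb1))$count
  }
  if (!is.null(cache)) cache[[key]] <- score
  score
}

.resources_key <- function(engine, resources) {
  if (engine == "eplet") {
    paste0("pc=", isTRUE(resources$per_class))
  } else {
    paste0("thr=", if (is.null(resources$ic50_threshold)) 1000
                   else resources$ic50_threshold,
           ";w=", if (is.null(resources$window)) 15L else resources$window,
           ";per=", isTRUE(resources$count_per_drb1))
  }
}

#' Frequency-weighted epitope value for a donor-recipient couple
#'
#' The headline quantity: both phenotypes are imputed independently to
#' weighted candidate genotype lists; the epitope engine is evaluated on
#' every (donor candidate x recipient candidate) pair over the full
#' imputed five-locus genotypes (loci omitted from the input are filled
#' in by the imputation); and each integer score is weighted by the
#' product of the two candidates' normalized frequencies. The weighted
#' scores are summed into the expected epitope value. Deterministic given
#' its inputs.
#'
#' @param donor_phenotype,recipient_phenotype `hla_phenotype` objects.
#' @param table An `hla_freq_table`.
#' @param map An `hla_serology_map`.
#' @param engine `"pirche2"` or `"eplet"`.
#' @param resources List of engine resources: `registry` (eplet engine);
#'   `proteins`, optionally `predictor`, `ic50_threshold`, `window`,
#'   `count_per_drb1` (PIRCHE-II engine); optionally `per_class` (eplet).
#' @param cache Optional score cache from [new_score_cache()].
#' @param ... Passed to [extrapolate()] (`hw_factor`,
#'   `single_as_unknown`, `max_candidates`).
#' @return An object of class `imputed_score`: list with
#'   `expected_value`, `engine`, `n_donor_candidates`,
#'   `n_recipient_candidates`, `scheme_donor`, `scheme_recipient`, and
#'   the two imputations. Raises a typed condition (class
#'   `epimatch_unimputable`) when either side has no candidate genotype.
#' @export
imputed_epitope_value <- function(donor_phenotype, recipient_phenotype,
                                  table, map,
                                  engine = c("pirche2", "eplet"),
                                  resources, cache = NULL, ...) {
  engine <- match.arg(engine)
  imp_d <- extrapolate(donor_phenotype, table, map, ...)
  if (imp_d$unimputable) stop(.unimputable_error("donor", donor_phenotype))
  imp_r <- extrapolate(recipient_phenotype, table, map, ...)
  if (imp_r$unimputable) stop(.unimputable_error("recipient", recipient_phenotype))

  skey <- .resources_key(engine, resources)
  dc <- imp_d$candidates
  rc <- imp_r$candidates
  acols <- c(paste0("h1_", HLA_LOCI), paste0("h2_", HLA_LOCI))
  d_mat <- as.matrix(dc[, acols])
  r_mat <- as.matrix(rc[, acols])

  value <- 0
  for (i in seq_len(nrow(dc))) {
    d_alleles <- d_mat[i, ]
    for (j in seq_len(nrow(rc))) {
      s <- .engine_score(d_alleles, r_mat[j, ], engine, resources, cache, skey)
      value <- value + dc$weight[[i]] * rc$weight[[j]] * s
    }
  }
  structure(
    list(expected_value = value, engine = engine,
         n_donor_candidates = nrow(dc), n_recipient_candidates = nrow(rc),
         scheme_donor = imp_d$scheme, scheme_recipient = imp_r$scheme,
         imputation_donor = imp_d, imputation_recipient = imp_r),
    class = "imputed_score")
}

#' @export
print.imputed_score <- function(x, ...) {
  cat(sprintf(
    "<imputed_score> %s expected value %.4f (%d donor x %d recipient candidates, schemes [%d]/[%d])\n",
    x$engine, x$expected_value, x$n_donor_candidates,
    x$n_recipient_candidates, x$scheme_donor, x$scheme_recipient))
  invisible(x)
}

#' Score a couple under a typing-resolution scenario
#'
#' Given a couple with known true two-field genotypes, derives the input
#' typings a given scenario would provide and computes the weighted
#' epitope value from them:
#' \describe{
#'   \item{`split_both`}{serological split typing of both sides, all
#'     five loci (the observation group).}
#'   \item{`split_drop_C`}{split typing with HLA-C omitted from both
#'     sides.}
#'   \item{`split_drop_DQ`}{split typing with HLA-DQ omitted.}
#'   \item{`twofield_recipient_split_donor`}{two-field genotype of the
#'     recipient, split typing of the donor.}
#'   \item{`reference`}{no imputation: the plain integer engine score on
#'     the true genotypes.}
#' }
#'
#' @param couple List with elements `donor` and `recipient`, both
#'   `hla_genotype` objects (the truth).
#' @param scenario One of the scenario names above.
#' @inheritParams imputed_epitope_value
#' @return An `imputed_score`.
#' @export
scenario_score <- function(couple, table, map,
                           engine = c("pirche2", "eplet"), resources,
                           scenario = c("split_both", "split_drop_C",
                                        "split_drop_DQ",
                                        "twofield_recipient_split_donor",
                                        "reference"),
                           cache = NULL, ...) {
  engine <- match.arg(engine)
  scenario <- match.arg(scenario)
  if (scenario == "reference") {
    skey <- .resources_key(engine, resources)
    s <- .engine_score(genotype_alleles(couple$donor),
                       genotype_alleles(couple$recipient),
                       engine, resources, cache, skey)
    return(structure(
      list(expected_value = as.numeric(s), engine = engine,
           n_donor_candidates = 1L, n_recipient_candidates = 1L,
           scheme_donor = NA_integer_, scheme_recipient = NA_integer_,
           imputation_donor = NULL, imputation_recipient = NULL),
      class = "imputed_score"))
  }
  degr <- switch(scenario,
    split_both = c("split", "split"),
    split_drop_C = c("split_drop_C", "split_drop_C"),
    split_drop_DQ = c("split_drop_DQ", "split_drop_DQ"),
    twofield_recipient_split_donor = c("split", "twofield"))
  d_ph <- degrade(couple$donor, map, degr[[1L]])
  r_ph <- degrade(couple$recipient, map, degr[[2L]])
  imputed_epitope_value(d_ph, r_ph, table, map, engine = engine,
                        resources = resources, cache = cache, ...)
}
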