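## Virtual donor population: haplotype sampling from a frequency table
## and donor-recipient couple formation under the deceased-kidney
## allocation rule (at most 3 broad mismatches at HLA-A+B, at most 1 at
## HLA-DR).

#' Sample a virtual population from a haplotype frequency table
#'
#' Each individual receives two haplotypes drawn from the table. Under
#' the default `iid` policy every draw is independent with probability
#' proportional to frequency. The `finite_pool` policy discretizes the
#' table into a pool of haplotype copies (counts proportional to
#' frequency) and draws without replacement until the pool is exhausted —
#' the literal without-replacement reading, kept as an alternative; `iid`
#' is the statistically standard choice and the recommended default.
#'
#' @param table An `hla_freq_table`.
#' @param n Number of individuals.
#' @param seed Integer seed; the population is reproducible given it.
#' @param policy `"iid"` or `"finite_pool"`.
#' @param pool_size Number of haplotype copies in the finite pool
#'   (default `4 * n`, must be at least `2 * n`).
#' @return A data.frame of class `virtual_population` with columns `id`,
#'   `h1_A..h1_DQB1`, `h2_A..h2_DQB1`.
#' @export
sample_population <- function(table, n, seed = NULL,
                              policy = c("iid", "finite_pool"),
                              pool_size = NULL) {
  policy <- match.arg(policy)
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  nh <- nrow(table)
  if (policy == "iid") {
    draws <- sample.int(nh, size = 2L * n, replace = TRUE,
                        prob = table$freq)
  } else {
    if (is.null(pool_size)) pool_size <- 4L * n
    counts <- round(table$freq / sum(table$freq) * pool_size)
    pool <- rep.int(seq_len(nh), counts)
    if (length(pool) < 2L * n) {
      stop(sprintf(
        "finite pool exhausted: %d haplotype copies for %d draws",
        length(pool), 2L * n), call. = FALSE)
    }
    draws <- sample(pool, size = 2L * n, replace = FALSE)
  }
  h1 <- table[draws[seq_len(n)], HLA_LOCI, drop = FALSE]
  h2 <- table[draws[n + seq_len(n)], HLA_LOCI, drop = FALSE]
  names(h1) <- paste0("h1_", HLA_LOCI)
  names(h2) <- paste0("h2_", HLA_LOCI)
  out <- data.frame(id = seq_len(n), h1, h2, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("virtual_population", "data.frame"))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Genotype of one individual in a population
#' @param population A `virtual_population`.
#' @param i Row index or id.
#' @return An `hla_genotype`.
#' @export
individual_genotype <- function(population, i) {
  row <- population[population$id == i, ][1L, ]
  hla_genotype(
    stats::setNames(unlist(row[paste0("h1_", HLA_LOCI)], use.names = FALSE),
                    HLA_LOCI),
    stats::setNames(unlist(row[paste0("h2_", HLA_LOCI)], use.names = FALSE),
                    HLA_LOCI))
}

#' Count broad-level antigen mismatches at one locus
#'
#' Number of donor broad antigens at the locus absent from the
#' recipient's broad antigen set there. Antigen sets are used (the
#' serological convention): a homozygous donor contributes a single
#' antigen, so the count is 0-2.
#'
#' @param donor,recipient `hla_genotype` objects.
#' @param map An `hla_serology_map`.
#' @param locus One of the five loci.
#' @return Integer 0-2.
#' @export
count_broad_mismatches <- function(donor, recipient, map, locus) {
  d <- unique(serologize(c(donor[1L, locus], donor[2L, locus]), map, "broad"))
  r <- unique(serologize(c(recipient[1L, locus], recipient[2L, locus]),
                         map, "broad"))
  length(setdiff(d, r))
}

## Broad antigen set (as "a|b" sorted key parts) per individual per locus,
## vectorized over a population data.frame.
.broad_sets <- function(population, map, locus) {
  a1 <- population[[paste0("h1_", locus)]]
  a2 <- population[[paste0("h2_", locus)]]
  ua <- unique(c(a1, a2))
  b <- stats::setNames(serologize(ua, map, "broad"), ua)
  mapply(function(x, y) unique(c(x, y)), b[a1], b[a2],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Form donor-recipient couples under the allocation rule
#'
#' Pairs each recipient with one virtual donor such that, at serological
#' broad level, the couple has at most 3 mismatches at HLA-A plus HLA-B
#' and at most 1 mismatch at HLA-DR. Donors are drawn at random from the
#' donor population (with replacement across recipients); a drawn donor
#' violating the rule is rejected and redrawn until the criteria are met.
#'
#' @param donors,recipients `virtual_population` data.frames.
#' @param map An `hla_serology_map`.
#' @param seed Integer seed for reproducibility.
#' @param retry_cap Maximum rejected draws per recipient before a typed
#'   error names the recipient (guarantees termination on adversarial
#'   inputs).
#' @return A data.frame of class `couple_set` with columns
#'   `recipient_id`, `donor_id`, `mmA`, `mmB`, `mmDR`.
#' @export
form_couples <- function(donors, recipients, map, seed = NULL,
                         retry_cap = 1e5) {
  if (nrow(donors) == 0L || nrow(recipients) == 0L) {
    stop("donor and recipient populations must be nonempty", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  dA <- .broad_sets(donors, map, "A")
  dB <- .broad_sets(donors, map, "B")
  dDR <- .broad_sets(donors, map, "DRB1")
  rA <- .broad_sets(recipients, map, "A")
  rB <- .broad_sets(recipients, map, "B")
  rDR <- .broad_sets(recipients, map, "DRB1")

  nd <- nrow(donors)
  out <- data.frame(recipient_id = recipients$id,
                    donor_id = NA_integer_,
                    mmA = NA_integer_, mmB = NA_integer_,
                    mmDR = NA_integer_)
  for (r in seq_len(nrow(recipients))) {
    found <- FALSE
    for (try in seq_len(retry_cap)) {
      d <- sample.int(nd, 1L)
      mmA <- length(setdiff(dA[[d]], rA[[r]]))
      mmB <- length(setdiff(dB[[d]], rB[[r]]))
      mmDR <- length(setdiff(dDR[[d]], rDR[[r]]))
      if (mmA + mmB <= 3L && mmDR <= 1L) {
        out$donor_id[[r]] <- donors$id[[d]]
        out$mmA[[r]] <- mmA
        out$mmB[[r]] <- mmB
        out$mmDR[[r]] <- mmDR
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop(structure(
        class = c("epimatch_matching_failure", "error", "condition"),
        list(message = sprintf(
               "no acceptable donor found for recipient %s within %d draws",
               recipients$id[[r]], retry_cap),
             call = NULL, recipient = recipients$id[[r]])))
    }
  }
  structure(out, class = c("couple_set", "data.frame"))
}
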