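# Independent brute-force oracles. These deliberately share no code with
# the package internals: serology lookups go straight to the map's data
# frame, marginalization uses tapply, and candidate filtering works on
# logical hit matrices over all chromosome pairs.

LOCI5 <- c("A", "B", "C", "DRB1", "DQB1")

# allele -> does it project to this phenotype value? (two-field equality,
# or serological identity read off the raw map table)
oracle_projects <- function(allele, value, sermap_df) {
  if (grepl("*", value, fixed = TRUE)) return(allele == value)
  row <- sermap_df[sermap_df$allele == allele, ]
  if (nrow(row) == 0L) return(FALSE)
  if (value %in% sermap_df$split) row$split[[1L]] == value
  else row$broad[[1L]] == value
}

# expand a phenotype value into the set of alleles projecting to it
oracle_allele_set <- function(value, sermap_df) {
  if (grepl("*", value, fixed = TRUE)) return(value)
  if (value %in% sermap_df$split) {
    sermap_df$allele[sermap_df$split == value]
  } else {
    sermap_df$allele[sermap_df$broad == value]
  }
}

# haplotype-vs-phenotype matcher that expands values into allele sets
oracle_matches <- function(haplotype, phenotype, sermap_df) {
  for (loc in intersect(names(phenotype), names(haplotype))) {
    allowed <- unique(unlist(lapply(phenotype[[loc]], oracle_allele_set,
                                    sermap_df = sermap_df)))
    if (!haplotype[[loc]] %in% allowed) return(FALSE)
  }
  TRUE
}

# marginal frequency table of a locus block, by tapply over paste keys
oracle_marginals <- function(table, block) {
  df <- as.data.frame(table)
  key <- do.call(paste, c(df[block], sep = "\r"))
  sums <- tapply(df$freq, key, sum)
  parts <- strsplit(names(sums), "\r", fixed = TRUE)
  m <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(m) <- block
  m$freq <- as.numeric(sums)
  m
}

# exhaustive candidate enumeration: build every chromosome from the
# scheme's block marginals, take every unordered pair, keep pairs whose
# joint projection reproduces the phenotype exactly at covered loci
oracle_enumerate <- function(phenotype, table, map, scheme,
                             hw_factor = FALSE) {
  blocks <- list(
    list(LOCI5),
    list(c("A", "B", "C"), c("DRB1", "DQB1")),
    list("A", c("B", "C"), c("DRB1", "DQB1")),
    list("A", c("B", "C"), "DRB1", "DQB1"),
    list("A", "B", "C", "DRB1", "DQB1"))[[scheme]]
  sermap_df <- map$df
  margs <- lapply(blocks, oracle_marginals, table = table)
  idx <- expand.grid(lapply(margs, function(m) seq_len(nrow(m))),
                     KEEP.OUT.ATTRS = FALSE)
  n <- nrow(idx)
  chrom <- matrix(NA_character_, n, 5L, dimnames = list(NULL, LOCI5))
  cf <- rep(1, n)
  for (b in seq_along(blocks)) {
    m <- margs[[b]][idx[[b]], , drop = FALSE]
    for (loc in blocks[[b]]) chrom[, loc] <- m[[loc]]
    cf <- cf * m$freq
  }

  cov <- names(phenotype)
  # hit[[loc]][[v]] : logical over chromosomes
  valid <- matrix(TRUE, n, n)
  nonextra <- rep(TRUE, n)
  for (loc in cov) {
    vals <- phenotype[[loc]]
    hits <- lapply(vals, function(v) {
      vapply(chrom[, loc], oracle_projects, logical(1L),
             value = v, sermap_df = sermap_df, USE.NAMES = FALSE)
    })
    any_hit <- Reduce(`|`, hits)
    nonextra <- nonextra & any_hit
    for (h in hits) valid <- valid & outer(h, h, `|`)
  }
  valid <- valid & outer(nonextra, nonextra, `&`)

  keep <- which(valid & upper.tri(valid, diag = TRUE), arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(data.frame(key = character(0), freq = numeric(0),
                      stringsAsFactors = FALSE))
  }
  i <- keep[, 1L]; j <- keep[, 2L]
  freq <- cf[i] * cf[j]
  if (hw_factor) freq <- freq * ifelse(i == j, 1, 2)
  k1 <- apply(chrom[i, , drop = FALSE], 1L, paste, collapse = "|")
  k2 <- apply(chrom[j, , drop = FALSE], 1L, paste, collapse = "|")
  key <- ifelse(k1 <= k2, paste(k1, k2, sep = "+"), paste(k2, k1, sep = "+"))
  out <- data.frame(key = key, freq = freq, stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

# pair key of a package candidate row, for set comparison with the oracle
candidate_keys <- function(cand) {
  k1 <- do.call(paste, c(cand[paste0("h1_", LOCI5)], sep = "|"))
  k2 <- do.call(paste, c(cand[paste0("h2_", LOCI5)], sep = "|"))
  paste(k1, k2, sep = "+")
}

# literal set-algebra eplet count
oracle_eplet <- function(donor_alleles, recipient_alleles, registry) {
  d <- character(0)
  for (a in unique(donor_alleles)) d <- union(d, registry[[a]])
  r <- character(0)
  for (a in unique(recipient_alleles)) r <- union(r, registry[[a]])
  length(setdiff(d, r))
}

# straight-line PIRCHE-II pipeline: mismatch, scan, bind, self-filter,
# dedupe
oracle_pirche <- function(donor_alleles, recipient_alleles, proteins,
                          predictor, threshold = 1000, window = 15L) {
  donor_alleles <- unique(donor_alleles)
  recipient_alleles <- unique(recipient_alleles)
  drb1 <- recipient_alleles[grepl("^DRB1\\*", recipient_alleles)]
  mism <- donor_alleles[!donor_alleles %in% recipient_alleles]
  cores <- character(0)
  for (al in mism) {
    seqe <- proteins[[al]]
    len <- nchar(seqe)
    peps <- if (len <= window) seqe else
      vapply(1:(len - window + 1L),
             function(s) substr(seqe, s, s + window - 1L), character(1L))
    for (dr in drb1) {
      for (pep in peps) {
        pr <- predictor(pep, dr)
        if (pr$ic50 < threshold) {
          self <- FALSE
          for (ra in recipient_alleles) {
            if (grepl(pr$core, proteins[[ra]], fixed = TRUE)) {
              self <- TRUE
              break
            }
          }
          if (!self) cores <- c(cores, pr$core)
        }
      }
    }
  }
  length(unique(cores))
}

# hand-rolled type-7 quantile by sorting and index interpolation
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
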