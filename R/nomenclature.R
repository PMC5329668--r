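#' @keywords internal
"_PACKAGE"

## The five loci the method operates on. Other loci (DRB3/4/5, DQA1, DPB1)
## are rejected everywhere: the haplotype tables the imputation relies on
## cover exactly these five.
HLA_LOCI <- c("A", "B", "C", "DRB1", "DQB1")

#' Supported HLA loci
#'
#' The imputation pipeline is defined over the five classical loci covered
#' by published haplotype frequency tables: HLA-A, -B, -C, -DRB1 and -DQB1.
#'
#' @return Character vector of the five locus names.
#' @export
hla_loci <- function() HLA_LOCI

#' Normalize a two-field HLA allele name
#'
#' Accepts allele names with or without the locus prefix (`"A*01:01"` or
#' `"01:01"` with `locus = "A"`) and with or without leading zeros, and
#' returns the canonical `"LOCUS*NN:NN"` form. Normalization is idempotent.
#'
#' @param x Character vector of allele names.
#' @param locus Optional locus name used when `x` lacks the locus prefix,
#'   and checked against the prefix when present.
#' @return Character vector of normalized allele names.
#' @examples
#' normalize_allele("a*1:1")          # "A*01:01"
#' normalize_allele("02:01", "DRB1")  # "DRB1*02:01"
#' @export
normalize_allele <- function(x, locus = NULL) {
  x <- trimws(as.character(x))
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (grepl("*", s, fixed = TRUE)) {
      parts <- strsplit(s, "*", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        stop(sprintf("malformed allele name: '%s'", s), call. = FALSE)
      }
      loc <- toupper(parts[[1L]])
      fields <- parts[[2L]]
    } else {
      if (is.null(locus)) {
        stop(sprintf("allele '%s' has no locus prefix and no locus was given", s),
             call. = FALSE)
      }
      loc <- toupper(locus)
      fields <- s
    }
    if (!loc %in% HLA_LOCI) {
      stop(sprintf(
        "unsupported locus '%s' in allele '%s' (supported: %s)",
        loc, s, paste(HLA_LOCI, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(locus) && toupper(locus) != loc) {
      stop(sprintf("allele '%s' does not belong to locus %s", s, locus),
           call. = FALSE)
    }
    ff <- strsplit(fields, ":", fixed = TRUE)[[1L]]
    if (length(ff) != 2L || !all(grepl("^[0-9]+$", ff))) {
      stop(sprintf("malformed allele name: '%s' (expected LOCUS*NN:NN)", s),
           call. = FALSE)
    }
    out[[i]] <- sprintf("%s*%02d:%02d", loc,
                        as.integer(ff[[1L]]), as.integer(ff[[2L]]))
  }
  out
}

#' Locus of an allele name
#'
#' @param x Character vector of normalized allele names.
#' @return Character vector of locus names.
#' @export
allele_locus <- function(x) {
  vapply(strsplit(as.character(x), "*", fixed = TRUE),
         function(p) p[[1L]], character(1L))
}

## TRUE for values that are two-field allele names rather than serotypes.
is_allele_value <- function(x) grepl("*", x, fixed = TRUE)

#' Read an allele-to-serotype map
#'
#' Loads a serology dictionary from CSV with columns `allele,split,broad`
#' (one row per allele; the split-to-broad relation must be functional).
#' Real runs use a WMDA rel_dna_ser-style dictionary exported to this
#' layout; [generate_world()] produces synthetic ones. Results of any
#' serological-input analysis depend on this dictionary, so it is always
#' an explicit input, never built in.
#'
#' @param path Path to a CSV file with columns `allele`, `split`, `broad`.
#' @return An object of class `hla_serology_map` with lookup tables
#'   `allele_to_split` and `split_to_broad`.
#' @export
read_serology_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("allele", "split", "broad")
  if (!all(need %in% names(df))) {
    stop("serology map must have columns allele,split,broad", call. = FALSE)
  }
  serology_map(df$allele, df$split, df$broad)
}

#' Construct a serology map
#'
#' @param allele,split,broad Parallel character vectors: each allele, its
#'   split-level antigen, and the broad antigen the split belongs to.
#' @return An `hla_serology_map` object.
#' @export
serology_map <- function(allele, split, broad) {
  allele <- normalize_allele(allele)
  if (anyDuplicated(allele)) {
    stop("duplicate alleles in serology map", call. = FALSE)
  }
  a2s <- stats::setNames(as.character(split), allele)
  ## split -> broad must be a function
  s2b_df <- unique(data.frame(split = as.character(split),
                              broad = as.character(broad),
                              stringsAsFactors = FALSE))
  if (anyDuplicated(s2b_df$split)) {
    bad <- s2b_df$split[duplicated(s2b_df$split)][1L]
    stop(sprintf("split antigen '%s' maps to more than one broad antigen", bad),
         call. = FALSE)
  }
  s2b <- stats::setNames(s2b_df$broad, s2b_df$split)
  structure(
    list(allele_to_split = a2s, split_to_broad = s2b,
         df = data.frame(allele = allele, split = as.character(split),
                         broad = as.character(broad),
                         stringsAsFactors = FALSE)),
    class = "hla_serology_map")
}

#' Write a serology map to CSV
#'
#' @param map An `hla_serology_map`.
#' @param path Output CSV path.
#' @export
write_serology_map <- function(map, path) {
  utils::write.csv(map$df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map an allele or serotype to its serological antigen
#'
#' At `level = "split"` an allele maps to its split antigen; at
#' `level = "broad"` the split is collapsed further to its broad antigen.
#' Serotype input already at the requested (or coarser) level is returned
#' unchanged; a split serotype is collapsed when `level = "broad"`.
#'
#' @param value An allele name or serotype string (vectorized).
#' @param map An `hla_serology_map`.
#' @param level `"split"` or `"broad"`.
#' @return Character vector of serotypes.
#' @export
serologize <- function(value, map, level = c("split", "broad")) {
  level <- match.arg(level)
  value <- as.character(value)
  out <- character(length(value))
  for (i in seq_along(value)) {
    v <- value[[i]]
    if (is_allele_value(v)) {
      v <- normalize_allele(v)
      if (!v %in% names(map$allele_to_split)) {
        stop(sprintf("allele '%s' has no serotype mapping", v), call. = FALSE)
      }
      sp <- map$allele_to_split[[v]]
      out[[i]] <- if (level == "split") sp else .split_to_broad(sp, map)
    } else if (v %in% names(map$split_to_broad)) {
      out[[i]] <- if (level == "split") v else .split_to_broad(v, map)
    } else if (v %in% map$split_to_broad) {
      if (level == "split") {
        stop(sprintf("broad antigen '%s' cannot be refined to split level", v),
             call. = FALSE)
      }
      out[[i]] <- v
    } else {
      stop(sprintf("value '%s' is not mapped by the serology map", v),
           call. = FALSE)
    }
  }
  out
}

.split_to_broad <- function(split, map) {
  b <- map$split_to_broad[[split]]
  if (is.null(b) || is.na(b)) {
    stop(sprintf("split antigen '%s' has no broad mapping", split),
         call. = FALSE)
  }
  b
}

## Level of a phenotype value: "allele", "split" or "broad".
value_level <- function(v, map) {
  if (is_allele_value(v)) return("allele")
  if (v %in% names(map$split_to_broad)) return("split")
  if (v %in% map$split_to_broad) return("broad")
  stop(sprintf("value '%s' is not mapped by the serology map", v),
       call. = FALSE)
}

#' Construct a phenotype
#'
#' A phenotype is the per-locus unordered set of typing values for one
#' individual: serotypes (split or broad) or two-field alleles, one or two
#' values per locus, with loci allowed to be absent. A single value at a
#' locus is read as homozygous at the typed resolution.
#'
#' @param ... Named per-locus character vectors of 1-2 typing values, or a
#'   single named list.
#' @return An object of class `hla_phenotype` (a named list).
#' @examples
#' hla_phenotype(A = c("A1", "A2"), B = "B7", DRB1 = c("DR1", "DR4"))
#' @export
hla_phenotype <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1L]]) && is.null(names(vals))) {
    vals <- vals[[1L]]
  }
  if (is.null(names(vals)) || any(names(vals) == "")) {
    stop("phenotype loci must be named", call. = FALSE)
  }
  bad <- setdiff(names(vals), HLA_LOCI)
  if (length(bad)) {
    stop(sprintf("unsupported loci in phenotype: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  vals <- lapply(vals, function(v) {
    v <- unique(as.character(v))
    if (length(v) < 1L || length(v) > 2L) {
      stop("each phenotype locus must carry 1 or 2 distinct values",
           call. = FALSE)
    }
    ifelse(is_allele_value(v), normalize_allele(v), v)
  })
  structure(vals[intersect(HLA_LOCI, names(vals))], class = "hla_phenotype")
}

#' @export
print.hla_phenotype <- function(x, ...) {
  cat("<hla_phenotype>\n")
  for (loc in names(x)) {
    cat(sprintf("  %-5s %s\n", loc, paste(x[[loc]], collapse = " / ")))
  }
  invisible(x)
}

#' Construct a five-locus genotype
#'
#' @param h1,h2 Named character vectors of alleles, one per locus (names
#'   must cover `hla_loci()`), describing the two chromosomes.
#' @return A 2 x 5 character matrix of class `hla_genotype` (rows =
#'   haplotypes, columns = loci).
#' @export
hla_genotype <- function(h1, h2) {
  h1 <- .as_haplotype(h1)
  h2 <- .as_haplotype(h2)
  g <- rbind(h1, h2)
  dimnames(g) <- list(NULL, HLA_LOCI)
  class(g) <- c("hla_genotype", class(g))
  g
}

.as_haplotype <- function(h) {
  if (is.null(names(h))) {
    if (length(h) != 5L) stop("haplotype must have 5 named alleles", call. = FALSE)
    names(h) <- HLA_LOCI
  }
  if (!all(HLA_LOCI %in% names(h))) {
    stop("haplotype must cover all of A, B, C, DRB1, DQB1", call. = FALSE)
  }
  h <- h[HLA_LOCI]
  stats::setNames(normalize_allele(unname(h), NULL), HLA_LOCI)
}

## All alleles carried by a genotype (10 values incl. duplicates) as a
## character vector; accepts an hla_genotype matrix or a plain character
## vector of allele names.
genotype_alleles <- function(g) {
  if (is.matrix(g)) as.character(g) else normalize_allele(as.character(g))
}

#' Project a genotype to a phenotype
#'
#' Converts a full genotype to the per-locus value sets seen at a given
#' typing resolution, collapsing equal values (homozygosity at the typed
#' level yields a single value). Loci outside `loci` are absent from the
#' result, which is how locus-omission inputs are produced.
#'
#' @param genotype An `hla_genotype`.
#' @param map An `hla_serology_map` (unused for `level = "twofield"`).
#' @param level `"split"`, `"broad"` or `"twofield"`.
#' @param loci Loci to keep (default all five).
#' @return An `hla_phenotype`.
#' @export
phenotype_of <- function(genotype, map = NULL,
                         level = c("split", "broad", "twofield"),
                         loci = hla_loci()) {
  level <- match.arg(level)
  loci <- match.arg(loci, HLA_LOCI, several.ok = TRUE)
  vals <- list()
  for (loc in intersect(HLA_LOCI, loci)) {
    al <- c(genotype[1L, loc], genotype[2L, loc])
    v <- if (level == "twofield") al else serologize(al, map, level)
    vals[[loc]] <- unique(unname(v))
  }
  do.call(hla_phenotype, vals)
}

#' Read a haplotype frequency table
#'
#' Parses a CSV of five-locus haplotypes with population frequencies —
#' the imputation prior. Two dialects are supported: `"fixtures"`
#' (columns `A,B,C,DRB1,DQB1,freq`) and `"nmdp"` (NMDP-style columns
#' `A,B,C,DRB1,DQB1` in any case plus a frequency column named `freq`,
#' `frequency` or ending in `_freq`). Allele names are normalized; input
#' row order is kept in the table's metadata for reproducibility.
#'
#' @param path Path to the CSV file (or a connection).
#' @param dialect Column-naming dialect, `"fixtures"` or `"nmdp"`.
#' @param source,population Optional metadata labels.
#' @return A data.frame of class `hla_freq_table` with columns
#'   `A,B,C,DRB1,DQB1,freq`.
#' @export
read_haplotype_frequencies <- function(path, dialect = c("fixtures", "nmdp"),
                                       source = NA_character_,
                                       population = NA_character_) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "nmdp") {
    names(df) <- toupper(names(df))
    fcol <- grep("^FREQ$|^FREQUENCY$|_FREQ$", names(df), value = TRUE)
    if (length(fcol) != 1L) {
      stop("could not identify a unique frequency column (nmdp dialect)",
           call. = FALSE)
    }
    names(df)[names(df) == fcol] <- "freq"
    names(df)[names(df) == "DRB1"] <- "DRB1"  # already upper
  }
  if (!all(c(HLA_LOCI, "freq") %in% names(df))) {
    stop("frequency table must have columns A,B,C,DRB1,DQB1 and freq",
         call. = FALSE)
  }
  hla_freq_table(df[, c(HLA_LOCI, "freq")], source = source,
                 population = population)
}

#' Construct and validate a haplotype frequency table
#'
#' @param df Data frame with columns `A,B,C,DRB1,DQB1,freq`.
#' @param source,population Optional metadata labels.
#' @param tol Tolerance above 1 allowed for the frequency sum (published
#'   tables are truncated, so sums below 1 are expected and fine).
#' @return A data.frame of class `hla_freq_table`.
#' @export
hla_freq_table <- function(df, source = NA_character_,
                           population = NA_character_, tol = 1e-6) {
  for (i in seq_along(HLA_LOCI)) {
    loc <- HLA_LOCI[[i]]
    df[[loc]] <- tryCatch(
      normalize_allele(df[[loc]], loc),
      error = function(e) {
        stop(sprintf("frequency table, column %s: %s", loc, conditionMessage(e)),
             call. = FALSE)
      })
  }
  df$freq <- as.numeric(df$freq)
  if (any(!is.finite(df$freq)) || any(df$freq <= 0)) {
    bad <- which(!is.finite(df$freq) | df$freq <= 0)[1L]
    stop(sprintf("nonpositive frequency in row %d", bad), call. = FALSE)
  }
  key <- do.call(paste, c(df[HLA_LOCI], sep = "|"))
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate haplotype in row %d: %s", bad, key[[bad]]),
         call. = FALSE)
  }
  if (sum(df$freq) > 1 + tol) {
    stop(sprintf("haplotype frequencies sum to %.6f > 1", sum(df$freq)),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("hla_freq_table", "data.frame"),
            source = source, population = population,
            input_order = key)
}

#' Write a haplotype frequency table to CSV
#'
#' @param table An `hla_freq_table`.
#' @param path Output CSV path.
#' @export
write_haplotype_frequencies <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c(HLA_LOCI, "freq")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a typing (phenotype) from JSON
#'
#' Format: `{"id": ..., "loci": {"A": ["A2","A3"], ...},
#' "resolution": "split"|"two-field"|"mixed"}`. The `resolution` field is
#' informative; the value strings themselves determine how each locus is
#' interpreted.
#'
#' @param path Path to the JSON file.
#' @return A list with elements `id`, `phenotype` (an `hla_phenotype`) and
#'   `resolution`.
#' @export
read_typing <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$loci)) stop("typing JSON must have a 'loci' object", call. = FALSE)
  loci <- lapply(x$loci, function(v) as.character(unlist(v)))
  list(id = if (is.null(x$id)) NA_character_ else as.character(x$id),
       phenotype = hla_phenotype(loci),
       resolution = if (is.null(x$resolution)) NA_character_
                    else as.character(x$resolution))
}

#' Write a typing (phenotype) to JSON
#'
#' @param phenotype An `hla_phenotype`.
#' @param path Output path.
#' @param id Identifier stored in the file.
#' @param resolution Resolution label stored in the file.
#' @export
write_typing <- function(phenotype, path, id = "typing",
                         resolution = "mixed") {
  jsonlite::write_json(
    list(id = id, loci = lapply(unclass(phenotype), as.list),
         resolution = resolution),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read allele protein sequences from FASTA
#'
#' Headers must be (normalizable) two-field allele names.
#'
#' @param path FASTA file path.
#' @return Named character vector: allele name -> amino-acid sequence.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- normalize_allele(sub("\\s.*$", "", names(seqs)))
  .validate_proteins(seqs)
  seqs
}

#' Write allele protein sequences to FASTA
#'
#' @param proteins Named character vector (allele -> sequence).
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

.validate_proteins <- function(seqs) {
  if (any(nchar(seqs) == 0L)) {
    stop("empty protein sequence in FASTA", call. = FALSE)
  }
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (!all(ok)) {
    stop(sprintf("non-standard residues in sequence for %s",
                 names(seqs)[!ok][1L]), call. = FALSE)
  }
  invisible(seqs)
}

#' Read an eplet registry from CSV
#'
#' Long format, columns `allele,eplet`: one row per (allele, eplet)
#' annotation, as exported from an HLAMatchmaker-style registry.
#'
#' @param path CSV file path.
#' @return Named list: allele -> character vector of eplet names.
#' @export
read_eplet_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "eplet") %in% names(df))) {
    stop("eplet registry must have columns allele,eplet", call. = FALSE)
  }
  df$allele <- normalize_allele(df$allele)
  if (any(!nzchar(df$eplet))) stop("empty eplet name in registry", call. = FALSE)
  split(as.character(df$eplet), df$allele)
}

#' Write an eplet registry to CSV
#'
#' @param registry Named list: allele -> character vector of eplet names.
#' @param path Output CSV path.
#' @export
write_eplet_registry <- function(registry, path) {
  df <- data.frame(
    allele = rep(names(registry), lengths(registry)),
    eplet = unlist(registry, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
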