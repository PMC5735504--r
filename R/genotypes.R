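#' Construct a genotype matrix
#'
#' A genotype matrix holds marker calls for a mapping population: one row per
#' marker, one column per individual. Calls are coded `"A"` and `"B"` for the
#' two parental alleles, `"H"` for heterozygous, and `NA` for missing.
#'
#' @param calls character matrix of calls in `{"A","B","H",NA}`, markers in
#'   rows, individuals in columns.
#' @param marker_names unique marker names (defaults to rownames of `calls`).
#' @param individual_ids unique individual ids (defaults to colnames).
#' @param cross_type one of `"riself"`, `"f2"`, `"bc"`, `"unknown"`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, marker_names = rownames(calls),
                            individual_ids = colnames(calls),
                            cross_type = c("unknown", "riself", "f2", "bc")) {
  cross_type <- match.arg(cross_type)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(nrow(calls)))
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(ncol(calls)))
  marker_names <- as.character(marker_names)
  individual_ids <- as.character(individual_ids)
  if (length(marker_names) != nrow(calls))
    stop("marker_names length must equal number of rows of calls")
  if (length(individual_ids) != ncol(calls))
    stop("individual_ids length must equal number of columns of calls")
  if (anyDuplicated(marker_names))
    stop("duplicate marker name: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  bad <- !(calls %in% c("A", "B", "H") | is.na(calls))
  if (any(bad)) {
    w <- which(bad)[1]
    stop(sprintf("illegal genotype code '%s' at marker %s, individual %s",
                 calls[w], marker_names[(w - 1) %% nrow(calls) + 1],
                 individual_ids[(w - 1) %/% nrow(calls) + 1]))
  }
  dimnames(calls) <- list(marker_names, individual_ids)
  structure(list(calls = calls, cross_type = cross_type),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals (%s)\n",
              nrow(x$calls), ncol(x$calls), x$cross_type))
  cat(sprintf("  missing: %.2f%%  het: %.2f%%\n",
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == "H", na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

default_coding <- c("A" = "A", "B" = "B", "H" = "H",
                    "-" = NA_character_, "NA" = NA_character_)

#' Read a genotype matrix from CSV
#'
#' Expects a header row of individual ids and one row per marker, with the
#' marker name in the first column. Tokens are translated through `coding`;
#' any token absent from `coding` is an error rather than being treated as
#' missing.
#'
#' @param path CSV file path.
#' @param coding named character vector mapping file tokens to
#'   `{"A","B","H",NA}`; defaults map `"A","B","H"` to themselves and `"-"`
#'   or `"NA"` to missing.
#' @param cross_type cross design of the population.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, coding = default_coding,
                           cross_type = c("unknown", "riself", "f2", "bc")) {
  cross_type <- match.arg(cross_type)
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype file needs a header and at least one marker row")
  fields <- strsplit(lines, ",", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[1]))
    stop(sprintf("ragged genotype file: row %d has %d fields, expected %d",
                 which(nfield != nfield[1])[1], nfield[nfield != nfield[1]][1],
                 nfield[1]))
  ids <- fields[[1]][-1]
  markers <- vapply(fields[-1], `[`, "", 1L)
  tokens <- do.call(rbind, lapply(fields[-1], function(f) f[-1]))
  tokens <- trimws(tokens)
  known <- tokens %in% names(coding)
  if (!all(known)) {
    w <- which(!known)[1]
    i <- (w - 1) %% nrow(tokens) + 1
    j <- (w - 1) %/% nrow(tokens) + 1
    stop(sprintf("unknown genotype token '%s' at marker %s (row %d), individual %s (column %d)",
                 tokens[w], markers[i], i, ids[j], j))
  }
  calls <- matrix(unname(coding[tokens]), nrow = nrow(tokens))
  genotype_matrix(calls, markers, ids, cross_type)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [read_genotypes()]: header row of individual ids, one row per
#' marker. Missing calls are written as `"-"`.
#'
#' @param g a [genotype_matrix()].
#' @param path output CSV path.
#' @param missing_token token used for missing calls.
#' @export
write_genotypes <- function(g, path, missing_token = "-") {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  calls[is.na(calls)] <- missing_token
  lines <- c(paste(c("marker", colnames(g$calls)), collapse = ","),
             paste(rownames(g$calls),
                   apply(calls, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Pre-filter markers before recombination-frequency estimation
#'
#' Applies three removal rules, in order: (1) in homozygous designs
#' (`riself`), markers whose fraction of `H` calls among non-missing calls
#' exceeds `max_het_fraction` are dropped, and surviving `H` calls are
#' recoded to missing; (2) markers whose call vector is identical to an
#' earlier marker's (missing matching missing) are dropped as duplicates;
#' (3) of any pair whose similarity — the fraction of agreeing calls among
#' mutually non-missing individuals — exceeds `similarity_threshold`, the
#' later marker is dropped. The earliest marker of a duplicate or similar
#' set is always the one kept.
#'
#' @param g a [genotype_matrix()].
#' @param similarity_threshold similarity above which the later marker of a
#'   pair is removed; default 1 removes only exact duplicates.
#' @param max_het_fraction maximum tolerated `H` fraction (homozygous
#'   designs only).
#' @return list with elements `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `filter_report` listing every removal and its cause).
#' @export
filter_markers <- function(g, similarity_threshold = 1.0,
                           max_het_fraction = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(similarity_threshold) || length(similarity_threshold) != 1 ||
      is.na(similarity_threshold) || similarity_threshold < 0 ||
      similarity_threshold > 1)
    stop("similarity_threshold must be a fraction in [0, 1]")
  if (max_het_fraction < 0 || max_het_fraction > 1)
    stop("max_het_fraction must be a fraction in [0, 1]")
  calls <- g$calls
  m_in <- nrow(calls)

  removed_het <- character(0)
  if (g$cross_type == "riself") {
    nh <- rowSums(calls == "H", na.rm = TRUE)
    nn <- rowSums(!is.na(calls))
    frac <- ifelse(nn > 0, nh / nn, 0)
    drop_het <- frac > max_het_fraction
    removed_het <- rownames(calls)[drop_het]
    calls <- calls[!drop_het, , drop = FALSE]
    calls[calls == "H"] <- NA_character_  # residual heterozygosity -> missing
  }

  # duplicates: identical call vectors, NA positions included
  key <- apply(calls, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  dup <- duplicated(key)
  removed_dup <- if (any(dup)) {
    first <- match(key[dup], key)
    data.frame(kept = rownames(calls)[first], removed = rownames(calls)[dup],
               stringsAsFactors = FALSE)
  } else data.frame(kept = character(0), removed = character(0))
  calls <- calls[!dup, , drop = FALSE]

  # similarity: agreeing / mutually non-missing, greedy keep-earliest
  removed_sim <- data.frame(kept = character(0), removed = character(0),
                            similarity = numeric(0))
  if (similarity_threshold < 1 && nrow(calls) > 1) {
    codes <- c("A", "B", "H")
    agree <- matrix(0, nrow(calls), nrow(calls))
    for (cc in codes) {
      ind <- (calls == cc) & !is.na(calls)
      storage.mode(ind) <- "double"
      agree <- agree + tcrossprod(ind)
    }
    nm <- !is.na(calls)
    storage.mode(nm) <- "double"
    both <- tcrossprod(nm)
    sim <- ifelse(both > 0, agree / both, 0)
    keep <- rep(TRUE, nrow(calls))
    for (j in 2:nrow(calls)) {
      earlier <- which(keep[seq_len(j - 1)])
      hit <- earlier[sim[earlier, j] > similarity_threshold]
      if (length(hit)) {
        keep[j] <- FALSE
        removed_sim <- rbind(removed_sim, data.frame(
          kept = rownames(calls)[hit[1]], removed = rownames(calls)[j],
          similarity = sim[hit[1], j]))
      }
    }
    calls <- calls[keep, , drop = FALSE]
  }

  out <- genotype_matrix(calls, cross_type = g$cross_type)
  report <- structure(list(
    removed_duplicates = removed_dup,
    removed_heterozygous = removed_het,
    removed_similarity = removed_sim,
    n_markers_in = m_in,
    n_markers_out = nrow(calls)), class = "filter_report")
  stopifnot(report$n_markers_out ==
              m_in - length(removed_het) - nrow(removed_dup) - nrow(removed_sim))
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d markers in, %d out\n",
              x$n_markers_in, x$n_markers_out))
  cat(sprintf("  heterozygous removed: %d\n", length(x$removed_heterozygous)))
  cat(sprintf("  duplicates removed:   %d\n", nrow(x$removed_duplicates)))
  cat(sprintf("  similarity removed:   %d\n", nrow(x$removed_similarity)))
  invisible(x)
}
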