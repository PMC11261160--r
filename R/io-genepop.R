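#' Read a Genepop file into a genotype matrix
#'
#' Supports the two-digit (`0101`) and three-digit (`001001`) diploid allele
#' codings. `Pop` blocks become population labels `pop1..popK`, unless the
#' title line carries the `pops=a,b,...` convention written by
#' [write_genepop()], in which case those labels are restored (Genepop itself
#' has no population-name field). All-zero codes
#' (`0000`/`000000`) map to missing. At each locus the numerically smaller
#' allele code is taken as the reference allele and the larger as the
#' alternate, so genotypes are counts of the larger code. Loci with more than
#' two observed alleles are dropped with a message.
#'
#' @param path Path to a Genepop file.
#' @return A [geno_matrix()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read Genepop file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) abort("Genepop file too short")

  pop_labels <- NULL
  if (grepl("pops=", lines[1], fixed = TRUE)) {
    pop_labels <- strsplit(sub(".*pops=", "", lines[1]), ",")[[1]]
  }

  is_pop <- tolower(lines) == "pop"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("Genepop file has no 'Pop' line")
  locus_lines <- lines[2:(first_pop - 1)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  L <- length(locus_names)

  ids <- character(0); pops <- character(0)
  rows <- list()
  pop_idx <- 0L
  width <- NA_integer_
  for (ln in lines[first_pop:length(lines)]) {
    if (tolower(ln) == "pop") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) abort(paste0("malformed Genepop individual line: ", ln))
    id <- trimws(paste(parts[-length(parts)], collapse = ","))
    toks <- strsplit(trimws(parts[length(parts)]), "\\s+")[[1]]
    if (length(toks) != L) {
      abort(sprintf("individual '%s' has %d loci, expected %d", id, length(toks), L))
    }
    w <- unique(nchar(toks))
    if (length(w) != 1 || !w %in% c(4L, 6L)) {
      abort("mixed or unsupported allele coding widths (need uniform 4- or 6-digit genotypes)")
    }
    if (is.na(width)) width <- w
    if (w != width) abort("mixed allele coding widths across individuals")
    lab <- if (!is.null(pop_labels) && pop_idx <= length(pop_labels)) {
      pop_labels[pop_idx]
    } else {
      paste0("pop", pop_idx)
    }
    ids <- c(ids, id); pops <- c(pops, lab)
    rows[[length(rows) + 1L]] <- toks
  }

  half <- width / 2L
  a1 <- vapply(rows, function(t) substr(t, 1, half), character(L))
  a2 <- vapply(rows, function(t) substr(t, half + 1, width), character(L))
  if (L == 1) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  A1 <- matrix(as.integer(a1), L, length(ids))  # loci x individuals
  A2 <- matrix(as.integer(a2), L, length(ids))
  A1[A1 == 0L] <- NA_integer_; A2[A2 == 0L] <- NA_integer_

  G <- matrix(NA_integer_, length(ids), L)
  keep <- rep(TRUE, L)
  for (j in seq_len(L)) {
    alleles <- sort(unique(stats::na.omit(c(A1[j, ], A2[j, ]))))
    if (length(alleles) > 2) { keep[j] <- FALSE; next }
    alt <- if (length(alleles) == 2) alleles[2] else Inf
    G[, j] <- (!is.na(A1[j, ]) & A1[j, ] == alt) + (!is.na(A2[j, ]) & A2[j, ] == alt)
    G[is.na(A1[j, ]) | is.na(A2[j, ]), j] <- NA_integer_
  }
  if (!all(keep)) {
    inform(sprintf("read_genepop: dropped %d locus/loci with >2 alleles", sum(!keep)))
    G <- G[, keep, drop = FALSE]; locus_names <- locus_names[keep]
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  geno_matrix(G,
              loci = tibble(locus = locus_names),
              individuals = tibble(id = ids, pop = pops))
}

#' Write a genotype matrix to a Genepop file
#'
#' Individuals are written grouped into `Pop` blocks by their population
#' label (blocks in order of first appearance); genotype 0 becomes `0101`,
#' 1 becomes `0102`, 2 becomes `0202`, missing becomes `0000` (three-digit
#' coding doubles the widths).
#'
#' @param x A [geno_matrix()].
#' @param path Output file path.
#' @param digits Allele coding width, 2 or 3.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, digits = 2, title = "ldne genotype export") {
  stopifnot(digits %in% c(2, 3))
  fmt <- function(a) formatC(a, width = digits, flag = "0")
  codes <- c(`0` = paste0(fmt(1), fmt(1)), `1` = paste0(fmt(1), fmt(2)),
             `2` = paste0(fmt(2), fmt(2)))
  missing_code <- paste0(fmt(0), fmt(0))

  out <- c(paste0(title, "; pops=", paste(unique(x$individuals$pop), collapse = ",")),
           x$loci$locus)
  for (p in unique(x$individuals$pop)) {
    out <- c(out, "Pop")
    for (i in which(x$individuals$pop == p)) {
      g <- x$G[i, ]
      tok <- ifelse(is.na(g), missing_code, codes[as.character(g)])
      out <- c(out, paste0(x$individuals$id[i], " ,  ", paste(tok, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
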