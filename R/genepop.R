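## GenePop file I/O. The classic layout: title line, one locus name per
## line (or comma-separated), then "Pop" blocks of "id , 001002 003003 ..."
## rows. 2- and 3-digit allele dialects are auto-detected on read; 00/000
## codes an untyped allele.

#' Read a GenePop file
#'
#' @param path GenePop text file.
#' @return a [GenotypeTable-class]; population ids are taken from the last
#'   individual label of each Pop block (the GenePop convention), falling
#'   back to pop1, pop2, ...
#' @export
readGenepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("not a GenePop file: too short")
  popAt <- which(toupper(lines) == "POP")
  if (!length(popAt)) stop("not a GenePop file: no Pop line found")
  hdr <- lines[2:(popAt[1] - 1)]
  loci <- trimws(unlist(strsplit(hdr, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  blocks <- Map(function(from, to) lines[seq(from + 1, to)],
                popAt, c(popAt[-1] - 1L, length(lines)))
  digits <- NULL
  pops <- character(0)
  genotypes <- list()
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    if (!length(rows)) stop("empty Pop block ", b)
    mat <- matrix(NA_integer_, length(rows), 2L * L)
    label <- ""
    for (i in seq_along(rows)) {
      ln <- which(lines == rows[i])[1]
      parts <- strsplit(rows[i], ",")[[1]]
      if (length(parts) < 2)
        stop("parse error at line ", ln, ": missing ',' separator")
      label <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(codes) != L)
        stop("parse error at line ", ln, ": expected ", L,
             " genotypes, found ", length(codes))
      w <- unique(nchar(codes))
      if (length(w) != 1 || !w %in% c(4L, 6L))
        stop("parse error at line ", ln,
             ": genotypes must be uniformly 4- or 6-character codes")
      dg <- w / 2L
      if (is.null(digits)) digits <- dg
      if (dg != digits)
        stop("parse error at line ", ln, ": mixed ", digits * 2, "/",
             dg * 2, "-character dialects")
      a1 <- as.integer(substr(codes, 1, digits))
      a2 <- as.integer(substr(codes, digits + 1, 2 * digits))
      a1[a1 == 0L] <- NA_integer_
      a2[a2 == 0L] <- NA_integer_
      mat[i, seq(1, 2 * L, by = 2)] <- a1
      mat[i, seq(2, 2 * L, by = 2)] <- a2
    }
    pops <- c(pops, if (nzchar(label)) label else paste0("pop", b))
    genotypes[[b]] <- mat
  }
  if (anyDuplicated(pops)) pops <- make.unique(pops)
  new("GenotypeTable", loci = loci, pops = pops, genotypes = genotypes,
      trueFreqs = list())
}

#' Write a GenotypeTable as a GenePop file
#'
#' @param table a [GenotypeTable-class].
#' @param path output file.
#' @param digits allele-code width (2 or 3); missing alleles are written as
#'   zeros (\code{000000} for a fully missing genotype).
#' @param title first line of the file.
#' @export
writeGenepop <- function(table, path, digits = 3,
                         title = "riverfrag genotypes") {
  if (!digits %in% c(2, 3)) stop("digits must be 2 or 3")
  maxCode <- suppressWarnings(max(unlist(table@genotypes), na.rm = TRUE))
  if (is.finite(maxCode) && maxCode >= 10^digits)
    stop("allele codes exceed the ", digits, "-digit dialect")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(table@loci, con)
  fmt <- paste0("%0", digits, "d")
  L <- length(table@loci)
  for (b in seq_along(table@pops)) {
    writeLines("Pop", con)
    g <- table@genotypes[[b]]
    for (i in seq_len(nrow(g))) {
      codes <- vapply(seq_len(L), function(l) {
        a <- g[i, c(2 * l - 1, 2 * l)]
        a[is.na(a)] <- 0L
        paste0(sprintf(fmt, a[1]), sprintf(fmt, a[2]))
      }, "")
      writeLines(paste0(table@pops[b], " ,  ", paste(codes, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
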