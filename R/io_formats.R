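# Readers and writers for the tabular formats the pipeline touches:
# GENEPOP, STRUCTURE two-row tables, TPS / CSV landmark files, FASTA and
# newick.  Genotypes travel as a long tibble ("geno_tbl"): one row per
# individual x locus with integer allele sizes a1, a2 (both NA = missing).

#' Build a genotype table
#'
#' @param data a data frame with columns `id`, `pop`, `locus`, `a1`, `a2`
#'   (integer allele sizes; both NA for a missing call)
#' @param loci optional locus ordering (default: order of appearance)
#' @param pops optional population-label ordering
#' @return a `geno_tbl` tibble
#' @export
genotype_tbl <- function(data, loci = NULL, pops = NULL) {
  stopifnot(all(c("id", "pop", "locus", "a1", "a2") %in% names(data)))
  out <- as_tibble(data)
  out$a1 <- as.integer(out$a1); out$a2 <- as.integer(out$a2)
  bad <- xor(is.na(out$a1), is.na(out$a2))
  if (any(bad)) stop("half-missing calls: a call must be fully present or fully missing")
  if (any(stats::na.omit(c(out$a1, out$a2)) <= 0))
    stop("allele sizes must be positive integers")
  if (any(is.na(out$pop) | out$pop == ""))
    stop("every individual needs a population label")
  attr(out, "loci") <- loci %||% unique(out$locus)
  attr(out, "pops") <- pops %||% unique(out$pop)
  class(out) <- c("geno_tbl", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

geno_loci <- function(gm) attr(gm, "loci") %||% unique(gm$locus)
geno_pops <- function(gm) attr(gm, "pops") %||% unique(gm$pop)

# Encode a geno_tbl into integer allele-index matrices for the C++ kernels.
# Returns list(ids, pop (integer), pop_levels, loci, alleles (n x 2L matrix of
# 1-based indices, 0 = missing), nall, sizes (list of sorted allele sizes)).
geno_encode <- function(gm, loci = NULL, pops = NULL) {
  loci <- loci %||% geno_loci(gm)
  pops <- pops %||% geno_pops(gm)
  ids <- unique(gm$id)
  n <- length(ids); L <- length(loci)
  alleles <- matrix(0L, n, 2L * L)
  sizes <- vector("list", L)
  ind <- match(gm$id, ids)
  loc <- match(gm$locus, loci)
  for (l in seq_len(L)) {
    rows <- which(loc == l)
    sz <- sort(unique(stats::na.omit(c(gm$a1[rows], gm$a2[rows]))))
    sizes[[l]] <- sz
    i1 <- match(gm$a1[rows], sz); i2 <- match(gm$a2[rows], sz)
    alleles[cbind(ind[rows], 2L * l - 1L)] <- ifelse(is.na(i1), 0L, i1)
    alleles[cbind(ind[rows], 2L * l)] <- ifelse(is.na(i2), 0L, i2)
  }
  popv <- gm$pop[match(ids, gm$id)]
  list(ids = ids, pop = match(popv, pops), pop_levels = pops,
       loci = loci, alleles = alleles,
       nall = vapply(sizes, length, integer(1)), sizes = sizes)
}

#' Keep only individuals with complete genotypes
#'
#' Drops every individual with at least one missing call and logs the
#' retention fraction.  Surviving genotypes are never altered.
#'
#' @param gm a `geno_tbl`
#' @return the filtered `geno_tbl`
#' @export
filter_complete <- function(gm) {
  incomplete <- unique(gm$id[is.na(gm$a1)])
  keep <- !(gm$id %in% incomplete)
  out <- gm[keep, , drop = FALSE]
  n0 <- length(unique(gm$id)); n1 <- length(unique(out$id))
  hz_log("INFO", "filter_complete: retained ", n1, "/", n0,
         " individuals (", sprintf("%.1f", 100 * n1 / max(n0, 1)), "%)")
  if (n1 == 0) warning("no individuals with complete genotypes remain")
  attr(out, "loci") <- geno_loci(gm)
  attr(out, "pops") <- intersect(geno_pops(gm), unique(out$pop))
  class(out) <- unique(c("geno_tbl", class(out)))
  out
}

#' Read a GENEPOP file
#'
#' Supports the standard dialect: a title line, one locus name per line (or a
#' single comma-separated line), `POP` separators, and 2- or 3-digit allele
#' codes with `00`/`000` meaning a missing call.
#'
#' @param path file path
#' @param pop_labels labels for the POP blocks in order; defaults to the
#'   configured three-region vocabulary, then `popN`
#' @return a `geno_tbl`
#' @export
read_genepop <- function(path, pop_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("GENEPOP parse error: file too short")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GENEPOP parse error: no POP line found")
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  loci <- loci[loci != ""]
  L <- length(loci)
  if (L == 0) stop("GENEPOP parse error: no loci declared (line 2)")

  if (is.null(pop_labels)) {
    defaults <- default_config()$populations
    nblocks <- sum(is_pop)
    pop_labels <- if (nblocks <= length(defaults)) defaults[seq_len(nblocks)]
                  else paste0("pop", seq_len(nblocks))
  }

  recs <- list(); blk <- 0L; block_n <- integer(0)
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) {
      blk <- blk + 1L; block_n[blk] <- 0L
      next
    }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2)
      stop("GENEPOP parse error at line ", i, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(genos) != L)
      stop("GENEPOP parse error at line ", i, ": ", length(genos),
           " genotype fields for ", L, " loci")
    w <- unique(nchar(genos))
    if (length(w) > 1 || !(w %in% c(4L, 6L)))
      stop("GENEPOP parse error at line ", i,
           ": allele-code width must be uniformly 2 or 3 digits")
    half <- w / 2
    a1 <- as.integer(substr(genos, 1, half))
    a2 <- as.integer(substr(genos, half + 1, w))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    recs[[length(recs) + 1L]] <- tibble(
      id = id, pop = pop_labels[blk], locus = loci, a1 = a1, a2 = a2)
    block_n[blk] <- block_n[blk] + 1L
  }
  if (blk == 0 || any(block_n == 0))
    stop("GENEPOP parse error: empty POP block")
  genotype_tbl(bind_rows(recs), loci = loci, pops = pop_labels[seq_len(blk)])
}

#' Write a GENEPOP file (3-digit allele codes)
#' @param gm a `geno_tbl`
#' @param path output path
#' @param title title line text
#' @return `path`, invisibly
#' @export
write_genepop <- function(gm, path, title = "hybridzone export") {
  enc <- geno_encode(gm)
  loci <- enc$loci
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, loci), con)
  wide <- tidyr::pivot_wider(gm, id_cols = c("id", "pop"),
                             names_from = "locus", values_from = c("a1", "a2"))
  for (p in enc$pop_levels) {
    rows <- wide[wide$pop == p, , drop = FALSE]
    if (nrow(rows) == 0) next
    writeLines("POP", con)
    for (i in seq_len(nrow(rows))) {
      g <- vapply(loci, function(l)
        paste0(fmt(rows[[paste0("a1_", l)]][i]), fmt(rows[[paste0("a2_", l)]][i])),
        character(1))
      writeLines(paste0(rows$id[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE-format genotype table (two rows per individual)
#'
#' Expects a header line of locus names, then two rows per individual:
#' `id pop allele...`, with -9 coding a missing allele.
#'
#' @param path file path
#' @param pop_labels optional mapping from the integer pop codes to labels
#' @return a `geno_tbl`
#' @export
read_structure <- function(path, pop_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  L <- length(loci)
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) %% 2 != 0)
    stop("STRUCTURE parse error: odd number of genotype rows")
  recs <- list()
  for (i in seq(1, length(body), by = 2)) {
    r1 <- body[[i]]; r2 <- body[[i + 1]]
    if (length(r1) != L + 2 || length(r2) != L + 2)
      stop("STRUCTURE parse error near row ", i + 1, ": expected ", L + 2, " fields")
    if (r1[1] != r2[1]) stop("STRUCTURE parse error: row pair id mismatch at row ", i + 1)
    a1 <- as.integer(r1[-(1:2)]); a2 <- as.integer(r2[-(1:2)])
    a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2); a1[miss] <- NA; a2[miss] <- NA
    pcode <- r1[2]
    recs[[length(recs) + 1L]] <- tibble(
      id = r1[1],
      pop = if (!is.null(pop_labels)) pop_labels[as.integer(pcode)] else pcode,
      locus = loci, a1 = a1, a2 = a2)
  }
  genotype_tbl(bind_rows(recs), loci = loci)
}

#' Write a STRUCTURE-format genotype table
#' @param gm a `geno_tbl`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(gm, path) {
  enc <- geno_encode(gm)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(enc$loci, collapse = " "), con)
  wide <- tidyr::pivot_wider(gm, id_cols = c("id", "pop"),
                             names_from = "locus", values_from = c("a1", "a2"))
  for (i in seq_len(nrow(wide))) {
    pcode <- match(wide$pop[i], enc$pop_levels)
    for (row in 1:2) {
      a <- vapply(enc$loci, function(l) {
        v <- wide[[paste0("a", row, "_", l)]][i]
        if (is.na(v)) -9L else as.integer(v)
      }, integer(1))
      writeLines(paste(c(wide$id[i], pcode, a), collapse = " "), con)
    }
  }
  invisible(path)
}

# ---- landmarks ----------------------------------------------------------

#' Build a landmark table
#' @param data data frame with columns `id`, `sex`, `pop`, `lm`, `x`, `y`
#' @param n_landmarks expected landmarks per specimen
#' @return a `wing_tbl` tibble
#' @export
landmark_tbl <- function(data, n_landmarks = 23) {
  out <- as_tibble(data)
  stopifnot(all(c("id", "sex", "pop", "lm", "x", "y") %in% names(out)))
  cnt <- table(out$id)
  if (any(cnt != n_landmarks))
    stop("format error: every specimen needs exactly ", n_landmarks, " landmarks")
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop("parse error: non-finite landmark coordinate")
  attr(out, "n_landmarks") <- n_landmarks
  class(out) <- c("wing_tbl", class(out))
  out
}

#' Read wing landmarks (TPS or CSV dialect)
#'
#' TPS dialect: `LM=23` blocks of `x y` lines followed by `ID=` (and the
#' optional `SEX=` / `POP=` records this package writes).  CSV dialect: one
#' row per specimen with `id`, `sex`, `pop`, `x1`,`y1`,...,`x23`,`y23`.
#' Coordinates survive a write/read cycle exactly (decimal text).
#'
#' @param path file path
#' @param dialect "tps" or "csv" (default: guessed from the extension)
#' @param n_landmarks landmarks per specimen
#' @return a `wing_tbl`
#' @export
read_landmarks <- function(path, dialect = NULL, n_landmarks = 23) {
  dialect <- dialect %||% (if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv")
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    xc <- paste0("x", seq_len(n_landmarks)); yc <- paste0("y", seq_len(n_landmarks))
    if (!all(c(xc, yc) %in% names(df)))
      stop("format error: CSV needs columns ", xc[1], ",", yc[1], ",...")
    long <- tibble(
      id = rep(as.character(df$id), each = n_landmarks),
      sex = rep(as.character(df$sex %||% "unknown"), each = n_landmarks),
      pop = rep(as.character(df$pop %||% "unknown"), each = n_landmarks),
      lm = rep(seq_len(n_landmarks), nrow(df)),
      x = as.numeric(t(as.matrix(df[, xc]))),
      y = as.numeric(t(as.matrix(df[, yc]))))
    return(landmark_tbl(long, n_landmarks))
  }
  lines <- readLines(path, warn = FALSE)
  recs <- list(); i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) {
      k <- as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE))
      if (k != n_landmarks)
        stop("format error at line ", i, ": LM=", k, ", expected ", n_landmarks)
      coords <- strsplit(trimws(lines[i + seq_len(k)]), "\\s+")
      xy <- t(vapply(coords, function(v) {
        z <- suppressWarnings(as.numeric(v[1:2]))
        if (any(is.na(z))) stop("parse error: non-numeric coordinate near line ", i)
        z
      }, numeric(2)))
      i <- i + k + 1
      id <- NA_character_; sex <- "unknown"; pop <- "unknown"
      while (i <= length(lines) && !grepl("^LM\\s*=", trimws(lines[i]), ignore.case = TRUE)) {
        kv <- trimws(lines[i])
        if (grepl("^ID\\s*=", kv, ignore.case = TRUE)) id <- sub("^ID\\s*=\\s*", "", kv, ignore.case = TRUE)
        if (grepl("^SEX\\s*=", kv, ignore.case = TRUE)) sex <- sub("^SEX\\s*=\\s*", "", kv, ignore.case = TRUE)
        if (grepl("^POP\\s*=", kv, ignore.case = TRUE)) pop <- sub("^POP\\s*=\\s*", "", kv, ignore.case = TRUE)
        i <- i + 1
      }
      if (is.na(id)) id <- paste0("spec", length(recs) + 1)
      recs[[length(recs) + 1L]] <- tibble(
        id = id, sex = sex, pop = pop, lm = seq_len(k),
        x = xy[, 1], y = xy[, 2])
    } else i <- i + 1
  }
  if (length(recs) == 0) stop("format error: no LM= blocks found")
  landmark_tbl(bind_rows(recs), n_landmarks)
}

#' Write wing landmarks (TPS or CSV dialect)
#' @param lm a `wing_tbl`
#' @param path output path
#' @param dialect "tps" or "csv" (default from extension)
#' @return `path`, invisibly
#' @export
write_landmarks <- function(lm, path, dialect = NULL) {
  dialect <- dialect %||% (if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv")
  k <- attr(lm, "n_landmarks") %||% max(lm$lm)
  ids <- unique(lm$id)
  if (dialect == "csv") {
    wide <- do.call(rbind, lapply(ids, function(s) {
      d <- lm[lm$id == s, ][order(lm$lm[lm$id == s]), ]
      row <- data.frame(id = s, sex = d$sex[1], pop = d$pop[1])
      for (j in seq_len(k)) { row[[paste0("x", j)]] <- d$x[j]; row[[paste0("y", j)]] <- d$y[j] }
      row
    }))
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w"); on.exit(close(con))
  for (s in ids) {
    d <- lm[lm$id == s, ][order(lm$lm[lm$id == s]), ]
    writeLines(paste0("LM=", k), con)
    writeLines(paste(format(d$x, digits = 17, trim = TRUE, scientific = FALSE),
                     format(d$y, digits = 17, trim = TRUE, scientific = FALSE)), con)
    writeLines(paste0("ID=", s), con)
    writeLines(paste0("SEX=", d$sex[1]), con)
    writeLines(paste0("POP=", d$pop[1]), con)
  }
  invisible(path)
}

# ---- sequences and trees ------------------------------------------------

#' Read aligned haplotype sequences from FASTA
#'
#' Headers may be `id` or `id pop`; all sequences must share one length and
#' use the A/C/G/T/N alphabet.
#'
#' @param path FASTA path
#' @return a `seq_tbl` tibble with columns id, pop, seq
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste0, character(1), collapse = ""))
  hdr <- names(dna)
  id <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1)
  pop <- vapply(strsplit(hdr, "\\s+"), function(v) if (length(v) > 1) v[2] else "unknown",
                character(1))
  sequence_tbl(tibble(id = id, pop = pop, seq = seqs))
}

#' Build a sequence table
#' @param data data frame with columns `id`, `pop`, `seq`
#' @return a `seq_tbl`
#' @export
sequence_tbl <- function(data) {
  out <- as_tibble(data)
  stopifnot(all(c("id", "pop", "seq") %in% names(out)))
  out$seq <- toupper(out$seq)
  if (length(unique(nchar(out$seq))) != 1)
    stop("sequences must all have equal length")
  if (any(grepl("[^ACGTN]", out$seq)))
    stop("sequence alphabet restricted to A/C/G/T/N")
  class(out) <- c("seq_tbl", class(out))
  out
}

#' Write sequences to FASTA (headers `id pop`)
#' @param ss a `seq_tbl`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(ss, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(ss)))
    writeLines(c(paste0(">", ss$id[i], " ", ss$pop[i]), ss$seq[i]), con)
  invisible(path)
}

#' Write a tree as newick text
#' @param tree an `ape` phylo object
#' @param path optional output path; when NULL the newick string is returned
#' @return the newick string, invisibly when written to file
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Read a newick tree
#' @param path file path or a newick string
#' @return an `ape` phylo object
#' @export
read_newick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}
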