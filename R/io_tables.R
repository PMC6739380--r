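#' Read a 6-column PED pedigree
#'
#' Standard whitespace-delimited PED: family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), phenotype (1 = unaffected,
#' 2 = affected). Phenotype codes other than 1/2 are rejected: the discordant
#' design needs a binary phenotype.
#'
#' @param path Path to the PED file.
#' @param strict If `TRUE` (default), a family lacking an affected or a
#'   non-affected member is an error; otherwise a warning.
#' @return A `data.frame` of class `sibseg_pedigree` with columns
#'   `family_id, individual_id, father_id, mother_id, sex, phenotype`
#'   (`phenotype` is `"affected"` or `"non_affected"`).
#' @export
read_pedigree <- function(path, strict = TRUE) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L) stop("PED file must have 6 columns, found ", ncol(ped))
  names(ped) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  as_pedigree(ped, strict = strict)
}

#' Construct a pedigree from a data frame
#'
#' @param ped Data frame with columns `family_id`, `individual_id`,
#'   `phenotype` (PED codes `1`/`2` or the labels `non_affected`/`affected`);
#'   `father_id`, `mother_id`, `sex` optional.
#' @param strict See [read_pedigree()].
#' @return A `sibseg_pedigree` data frame.
#' @export
as_pedigree <- function(ped, strict = TRUE) {
  need <- c("family_id", "individual_id", "phenotype")
  if (!all(need %in% names(ped))) {
    stop("pedigree needs columns: ", paste(setdiff(need, names(ped)), collapse = ", "))
  }
  if (!"father_id" %in% names(ped)) ped$father_id <- "0"
  if (!"mother_id" %in% names(ped)) ped$mother_id <- "0"
  if (!"sex" %in% names(ped)) ped$sex <- "0"
  ph <- as.character(ped$phenotype)
  lab <- ifelse(ph %in% c("2", "affected"), "affected",
         ifelse(ph %in% c("1", "non_affected", "unaffected"), "non_affected",
                NA_character_))
  if (anyNA(lab)) {
    stop("unknown phenotype code(s): ",
         paste(unique(ph[is.na(lab)]), collapse = ", "),
         " (expected 1/2 or non_affected/affected)")
  }
  ped$phenotype <- lab
  if (anyDuplicated(ped$individual_id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  }
  ped <- ped[, c("family_id", "individual_id", "father_id", "mother_id",
                 "sex", "phenotype")]
  tab <- table(ped$family_id, ped$phenotype)
  incomplete <- rownames(tab)[rowSums(tab > 0) < 2L]
  if (length(incomplete)) {
    msg <- paste0("family without both phenotype groups: ",
                  paste(incomplete, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  class(ped) <- c("sibseg_pedigree", "data.frame")
  ped
}

#' @export
print.sibseg_pedigree <- function(x, ...) {
  cat("Pedigree:", length(unique(x$family_id)), "families,",
      nrow(x), "individuals (",
      sum(x$phenotype == "affected"), "affected /",
      sum(x$phenotype == "non_affected"), "non-affected )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a pedigree as 6-column PED
#'
#' @param ped A `sibseg_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  code <- ifelse(ped$phenotype == "affected", "2", "1")
  lines <- paste(ped$family_id, ped$individual_id, ped$father_id,
                 ped$mother_id, ped$sex, code, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant annotation TSV
#'
#' Tab-separated, with a header naming at least
#' `chrom, pos, ref, alt, gene, transcript_status, region, consequence`.
#' Optional columns: `gmaf`, `alt_pop_freq`, `known_id`, and pass-through
#' deleteriousness scores (`cadd`, `dann`, `provean`). Empty `gmaf`/`known_id`
#' cells become `NA`; a variant is *novel* when both are absent.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` keyed by `key` (one row per variant), with the
#'   columns above plus `novel` (logical).
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ""), comment.char = "")
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript_status",
            "region", "consequence")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation file missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (opt in c("gmaf", "alt_pop_freq", "known_id")) {
    if (!opt %in% names(ann)) ann[[opt]] <- rep(NA, nrow(ann))
  }
  ann$gmaf <- as.numeric(ann$gmaf)
  ann$alt_pop_freq <- as.numeric(ann$alt_pop_freq)
  bad <- !is.na(ann$gmaf) & (ann$gmaf < 0 | ann$gmaf > 0.5)
  if (any(bad)) {
    stop("gmaf outside [0, 0.5] for ", sum(bad),
         " row(s); a minor allele frequency cannot exceed 0.5")
  }
  ok_status <- ann$transcript_status %in% c("confirmed", "unconfirmed")
  if (!all(ok_status)) {
    stop("unknown transcript_status: ",
         paste(unique(ann$transcript_status[!ok_status]), collapse = ", "))
  }
  ok_region <- ann$region %in% c("coding", "utr5", "utr3")
  if (!all(ok_region)) {
    stop("unknown region: ", paste(unique(ann$region[!ok_region]), collapse = ", "))
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$key)) {
    stop("duplicate variant key(s) in annotation file: ",
         paste(unique(ann$key[duplicated(ann$key)]), collapse = ", "))
  }
  ann$novel <- is.na(ann$gmaf) & is.na(ann$known_id)
  ann
}

#' Write a variant annotation TSV
#'
#' @param ann Annotation data frame (as from [read_annotations()] or
#'   [simulate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "known_id", "gene",
                      "transcript_status", "region", "consequence",
                      "gmaf", "alt_pop_freq", "cadd", "dann", "provean"),
                    names(ann))
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per tab-delimited line: id, description, then gene symbols.
#' Duplicate genes within a set are removed with a warning; empty sets are
#' rejected.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_genesets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has no genes (need id, description, >=1 gene)")
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " has no genes")
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[1], "': duplicated gene(s) removed")
      genes <- unique(genes)
    }
    if (f[1] %in% names(sets)) stop("duplicate GMT set id: ", f[1])
    attr(genes, "description") <- f[2]
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene vectors (optionally with `description`
#'   attributes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genesets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    d <- attr(sets[[id]], "description")
    if (is.null(d)) d <- id
    paste(c(id, d, as.character(sets[[id]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments ignored. Used for the
#' curated immune-gene list, which is an input, never inferred.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols (case preserved; symbols are
#'   compared case-sensitively everywhere).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Parse a published-style genotype table
#'
#' Ingests rows shaped like the worked-example segregation tables: gene
#' symbol, SNP id, wild-type allele, then one genotype cell per subject
#' column (strings like `"A/A"` or `"C/T"`; blanks are missing). Cells are
#' unordered (`"C/T"` equals `"T/C"`) and are resolved against the wild-type
#' allele into `hom_ref`/`het`/`hom_alt`. Each row must use a single
#' consistent alternate allele.
#'
#' @param tab Data frame with columns `gene`, `snp_id`, `wild_type` and one
#'   column per subject.
#' @param subject_cols Names of the genotype columns. Defaults to every column
#'   not named `gene`, `snp_id`, `wild_type`, `block`, `immune` or `note`.
#' @return List with `rows` (`row_id, gene, snp_id, wild_type, alt_allele`)
#'   and `states` (rows x subjects character matrix of genotype states).
#'   Rows whose cells are all wild-type have `alt_allele = NA`. Duplicate
#'   (gene, snp_id) pairs are allowed (distinct printed rows) and flagged with
#'   a warning.
#' @export
parse_genotype_table <- function(tab, subject_cols = NULL) {
  meta <- c("gene", "snp_id", "wild_type", "block", "immune", "note")
  if (!all(c("gene", "snp_id", "wild_type") %in% names(tab))) {
    stop("genotype table needs columns gene, snp_id, wild_type")
  }
  if (is.null(subject_cols)) subject_cols <- setdiff(names(tab), meta)
  if (!length(subject_cols)) stop("no subject genotype columns found")

  n <- nrow(tab)
  states <- matrix("missing", n, length(subject_cols),
                   dimnames = list(NULL, subject_cols))
  alt_allele <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    wt <- as.character(tab$wild_type[i])
    for (j in seq_along(subject_cols)) {
      cell <- tab[[subject_cols[j]]][i]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      al <- strsplit(trimws(cell), "/", fixed = TRUE)[[1]]
      if (length(al) != 2L) {
        stop("row ", i, " (", tab$gene[i], " ", tab$snp_id[i],
             "): genotype cell '", cell, "' is not two '/'-separated alleles")
      }
      non_wt <- unique(al[al != wt])
      if (length(non_wt) > 1L ||
          (length(non_wt) == 1L && !is.na(alt_allele[i]) &&
           non_wt != alt_allele[i])) {
        stop("row ", i, " (", tab$gene[i], " ", tab$snp_id[i],
             "): inconsistent alternate allele in cell '", cell, "'")
      }
      if (length(non_wt) == 1L) alt_allele[i] <- non_wt
      n_alt <- sum(al != wt)
      states[i, j] <- c("hom_ref", "het", "hom_alt")[n_alt + 1L]
    }
  }
  rows <- data.frame(row_id = seq_len(n),
                     gene = as.character(tab$gene),
                     snp_id = as.character(tab$snp_id),
                     wild_type = as.character(tab$wild_type),
                     alt_allele = alt_allele, stringsAsFactors = FALSE)
  dup <- duplicated(paste(rows$gene, rows$snp_id))
  if (any(dup)) {
    warning("duplicated (gene, snp_id) row(s): ",
            paste(unique(paste(rows$gene, rows$snp_id)[dup]), collapse = ", "),
            " - kept as distinct printed rows")
  }
  list(rows = rows, states = states)
}
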