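# Tagged mRNA constructs: coding sequences, epitope tag designs, and the
# per-codon epitope profile that converts ribosome positions into spot
# intensity in units of mature protein (UMP).

#' Create a coding sequence
#'
#' @param nucleotides Nucleotide string over `{A,C,G,T,U}`; length must be a
#'   multiple of 3 and the sequence must contain no internal stop codon (a
#'   terminal stop is allowed and retained).
#' @param name Optional sequence name.
#' @return An object of class `coding_sequence` with fields `name`,
#'   `nucleotides`, `length_nt`, `codons`.
#' @export
#' @examples
#' cds <- coding_sequence("ATGGCTGCTTAA", name = "toy")
#' cds$length_nt
coding_sequence <- function(nucleotides, name = "unnamed") {
  nucleotides <- toupper(gsub("U", "T", nucleotides))
  if (!grepl("^[ACGT]*$", nucleotides))
    stopf("coding sequence contains non-ACGT/U characters")
  if (nchar(nucleotides) == 0L || nchar(nucleotides) %% 3 != 0)
    stopf("coding sequence length %d is not a positive multiple of 3",
          nchar(nucleotides))
  codons <- split_codons(nucleotides)
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS))
    stopf("coding sequence '%s' contains an internal stop codon", name)
  structure(list(name = name, nucleotides = nucleotides,
                 length_nt = nchar(nucleotides), codons = codons),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d NT (%d codons)\n",
              x$name, x$length_nt, length(x$codons)))
  invisible(x)
}

#' Generate a synthetic gene with prescribed codon usage
#'
#' Samples sense codons i.i.d. from `usage_weights` to the requested
#' nucleotide length. Stop codons are never drawn, so the result is a valid
#' open reading frame body; no start/stop bookkeeping is imposed.
#'
#' @param length_nt Gene length in nucleotides (multiple of 3).
#' @param usage_weights Named probability vector over sense codons; defaults
#'   to [human_codon_usage()].
#' @param seed Integer seed for reproducibility (optional).
#' @param name Sequence name.
#' @return A [coding_sequence()].
#' @export
#' @examples
#' g <- generate_synthetic_gene(1200, seed = 1)
#' g$length_nt
generate_synthetic_gene <- function(length_nt,
                                    usage_weights = human_codon_usage(),
                                    seed = NULL, name = NULL) {
  if (length_nt <= 0 || length_nt %% 3 != 0)
    stopf("length_nt = %s is not a positive multiple of 3", length_nt)
  usage_weights <- usage_weights[!(names(usage_weights) %in% STOP_CODONS)]
  if (any(usage_weights < 0) || sum(usage_weights) <= 0)
    stopf("usage_weights must be non-negative with positive sum")
  n_codons <- length_nt / 3
  codons <- with_seed(seed, sample(names(usage_weights), n_codons,
                                   replace = TRUE,
                                   prob = usage_weights / sum(usage_weights)))
  name <- name %||% sprintf("synth_%dnt", length_nt)
  coding_sequence(paste(codons, collapse = ""), name = name)
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file with one or more coding sequences.
#' @return A list of [coding_sequence()] objects.
#' @export
read_coding_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- names(set)
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    ids <- sub("^>\\s*", "", lines[idx])
    ids <- sub("\\s.*$", "", ids)
    grp <- cumsum(idx)
    seqs <- vapply(split(lines[!idx], grp[!idx]), paste, "", collapse = "")
    names(seqs) <- ids
  }
  mapply(coding_sequence, seqs, names(seqs), SIMPLIFY = FALSE)
}

# ---------------------------------------------------------------------------
# Tag designs

EPITOPE_FLAG <- "DYKDDDDK"
EPITOPE_FLAG_DEAD <- "DYKDGGDK"   # mutated, antibody-blind copy

# Lay n epitopes into a block of len_aa amino acids, linker-first: each
# epitope is preceded by a linker and completes at an evenly spaced codon.
layout_epitopes <- function(len_aa, n, ep_len = 8L) {
  if (n == 0L) return(integer(0))
  spacing <- floor(len_aa / n)
  if (spacing < ep_len)
    stopf("block of %d aa cannot hold %d epitopes of %d aa", len_aa, n, ep_len)
  spacing * seq_len(n)
}

#' Define an epitope tag design
#'
#' A tag is one or two blocks of amino acids (an N-terminal block translated
#' before the gene and/or a C-terminal block translated after it), each
#' containing linker-separated epitope repeats. The default is the 10x FLAG
#' design: ten `DYKDDDDK` epitopes in a 1011-NT (337-aa) N-terminal block.
#'
#' @param n_epitopes Number of epitope repeats (intact + dead).
#' @param epitope_aa Epitope amino-acid sequence.
#' @param placement `"N_terminal"`, `"C_terminal"`, or `"split"`.
#' @param length_nt Total tag length in nucleotides (multiple of 3).
#' @param n_back For `placement = "split"`, how many epitopes sit in the
#'   C-terminal block.
#' @return An object of class `tag_design` with per-epitope completion
#'   positions (`block`, `end_aa`) and `dead` flags.
#' @export
#' @examples
#' tag <- tag_design()        # 10x FLAG, 1011 NT, N-terminal
#' tag$length_nt
tag_design <- function(n_epitopes = 10L, epitope_aa = EPITOPE_FLAG,
                       placement = c("N_terminal", "C_terminal", "split"),
                       length_nt = 1011L, n_back = 0L) {
  placement <- match.arg(placement)
  if (length_nt %% 3 != 0) stopf("tag length_nt must be a multiple of 3")
  len_aa <- as.integer(length_nt / 3)
  ep_len <- nchar(epitope_aa)
  n_epitopes <- as.integer(n_epitopes)
  if (placement == "split") {
    if (n_back <= 0L || n_back >= n_epitopes)
      stopf("split placement needs 0 < n_back < n_epitopes")
    n_front <- n_epitopes - as.integer(n_back)
    # front block keeps the single-block spacing for its epitopes; the
    # remainder of the tag length moves to the C-terminus
    spacing <- if (n_epitopes > 0) floor(len_aa / n_epitopes) else 0L
    front_len <- spacing * n_front
    back_len <- len_aa - front_len
    ends <- data.frame(
      block = c(rep("front", n_front), rep("back", n_back)),
      end_aa = c(layout_epitopes(front_len, n_front, ep_len),
                 layout_epitopes(back_len, as.integer(n_back), ep_len)),
      stringsAsFactors = FALSE)
  } else if (placement == "N_terminal") {
    front_len <- len_aa; back_len <- 0L
    ends <- data.frame(block = rep("front", n_epitopes),
                       end_aa = layout_epitopes(len_aa, n_epitopes, ep_len),
                       stringsAsFactors = FALSE)
  } else {
    front_len <- 0L; back_len <- len_aa
    ends <- data.frame(block = rep("back", n_epitopes),
                       end_aa = layout_epitopes(len_aa, n_epitopes, ep_len),
                       stringsAsFactors = FALSE)
  }
  structure(list(n_epitopes = n_epitopes, epitope_aa = epitope_aa,
                 placement = placement, length_nt = as.integer(length_nt),
                 front_len_aa = as.integer(front_len),
                 back_len_aa = as.integer(back_len),
                 epitopes = ends, dead = rep(FALSE, n_epitopes)),
            class = "tag_design")
}

#' @export
print.tag_design <- function(x, ...) {
  cat(sprintf("<tag_design> %dx '%s' (%d intact), %s, %d NT\n",
              x$n_epitopes, x$epitope_aa, sum(!x$dead), x$placement,
              x$length_nt))
  invisible(x)
}

#' Derive a variant of the 10x N-terminal tag design
#'
#' The variants mirror common redesign strategies for hard-to-classify
#' construct pairs: move fluctuation signal to the 3' end, brighten, or dim.
#'
#' @param base The base [tag_design()] (10x, N-terminal).
#' @param variant One of `"split_3_to_C"` (relocate 3 epitopes to a
#'   C-terminal block), `"relocate_C"` (move the whole tag to the
#'   C-terminus), `"add_5"` (append 5 more epitopes, each preceded by two
#'   glycines), `"remove_5"` (mutate the last 5 epitopes to a dead,
#'   antibody-blind sequence; tag length unchanged).
#' @return A new `tag_design`.
#' @export
#' @examples
#' dim10 <- make_tag_variant(tag_design(), "remove_5")
#' sum(!dim10$dead)   # 5 intact epitopes left
make_tag_variant <- function(base,
                             variant = c("split_3_to_C", "relocate_C",
                                         "add_5", "remove_5")) {
  variant <- match.arg(variant)
  stopifnot(inherits(base, "tag_design"))
  if (base$placement != "N_terminal")
    stopf("tag variants are defined relative to the N-terminal base design")
  out <- switch(variant,
    split_3_to_C = tag_design(base$n_epitopes, base$epitope_aa,
                              placement = "split",
                              length_nt = base$length_nt, n_back = 3L),
    relocate_C = tag_design(base$n_epitopes, base$epitope_aa,
                            placement = "C_terminal",
                            length_nt = base$length_nt),
    add_5 = {
      ep_len <- nchar(base$epitope_aa)
      extra_aa <- 5L * (2L + ep_len)            # GG + epitope, five times
      x <- base
      x$n_epitopes <- base$n_epitopes + 5L
      x$length_nt <- base$length_nt + 3L * extra_aa
      x$front_len_aa <- base$front_len_aa + extra_aa
      new_ends <- base$front_len_aa + (2L + ep_len) * seq_len(5L)
      x$epitopes <- rbind(base$epitopes,
                          data.frame(block = "front", end_aa = new_ends,
                                     stringsAsFactors = FALSE))
      x$dead <- rep(FALSE, x$n_epitopes)
      x
    },
    remove_5 = {
      x <- base
      x$dead[(base$n_epitopes - 4L):base$n_epitopes] <- TRUE
      x
    })
  out
}

# Amino-acid sequence of one tag block ("front"/"back"): glycine-serine
# linker filler with epitopes placed so each completes at its end_aa; dead
# epitopes carry the mutated sequence.
tag_block_aa <- function(tag, block) {
  len <- if (block == "front") tag$front_len_aa else tag$back_len_aa
  if (len == 0L) return(character(0))
  aa <- rep(c("G", "S"), length.out = len)
  sel <- tag$epitopes$block == block
  ends <- tag$epitopes$end_aa[sel]
  dead <- tag$dead[sel]
  ep_len <- nchar(tag$epitope_aa)
  for (k in seq_along(ends)) {
    seq_aa <- if (dead[k]) EPITOPE_FLAG_DEAD else tag$epitope_aa
    aa[(ends[k] - ep_len + 1L):ends[k]] <- strsplit(seq_aa, "")[[1]]
  }
  aa
}

# ---------------------------------------------------------------------------
# Constructs

#' Assemble a tagged mRNA construct
#'
#' Concatenates the tag block(s) and gene into one open reading frame and
#' computes the epitope profile `f`: `f[j]` is the number of intact epitopes
#' fully translated when a ribosome sits at codon `j`, divided by the tag's
#' total epitope count, so a ribosome past the whole tag contributes exactly
#' 1 UMP (unit of mature protein).
#'
#' @param gene A [coding_sequence()].
#' @param tag A [tag_design()].
#' @return An object of class `nct_construct` with fields `name`, `gene`,
#'   `tag`, `codons`, `total_codons`, `L_mRNA_nt`, `L_tag_nt`,
#'   `epitope_profile` (UMP), `epitope_counts`.
#' @export
#' @examples
#' g <- generate_synthetic_gene(1200, seed = 1)
#' con <- build_construct(g, tag_design())
#' con$total_codons == (1200 + 1011) / 3
build_construct <- function(gene, tag) {
  stopifnot(inherits(gene, "coding_sequence"), inherits(tag, "tag_design"))
  front_aa <- tag_block_aa(tag, "front")
  back_aa <- tag_block_aa(tag, "back")
  codons <- c(preferred_codon(front_aa), gene$codons, preferred_codon(back_aa))
  total <- length(codons)
  stopifnot(total == (gene$length_nt + tag$length_nt) / 3)
  # epitope completion codon in construct coordinates
  n_gene <- length(gene$codons)
  end_codon <- ifelse(tag$epitopes$block == "front",
                      tag$epitopes$end_aa,
                      tag$front_len_aa + n_gene + tag$epitopes$end_aa)
  intact_ends <- sort(end_codon[!tag$dead])
  counts <- vapply(seq_len(total),
                   function(j) sum(intact_ends <= j), numeric(1))
  structure(list(name = gene$name, gene = gene, tag = tag, codons = codons,
                 total_codons = total,
                 L_mRNA_nt = gene$length_nt, L_tag_nt = tag$length_nt,
                 epitope_counts = counts,
                 epitope_profile = counts / max(tag$n_epitopes, 1L)),
            class = "nct_construct")
}

#' @export
print.nct_construct <- function(x, ...) {
  cat(sprintf(
    "<nct_construct> %s: %d NT gene + %d NT tag = %d codons, max %g UMP\n",
    x$name, x$L_mRNA_nt, x$L_tag_nt, x$total_codons,
    max(x$epitope_profile)))
  invisible(x)
}

#' Serialize a construct or tag design to JSON
#'
#' Records codon counts, tag layout and epitope completion positions (not
#' the full nucleotide sequence) for run manifests.
#'
#' @param x A `tag_design` or `nct_construct`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly the path when writing to file).
#' @export
construct_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "nct_construct")) {
    list(type = "construct", name = x$name, L_mRNA_nt = x$L_mRNA_nt,
         L_tag_nt = x$L_tag_nt, total_codons = x$total_codons,
         n_epitopes = x$tag$n_epitopes, placement = x$tag$placement,
         dead = x$tag$dead,
         epitope_completion_codons =
           which(diff(c(0, x$epitope_counts)) > 0))
  } else if (inherits(x, "tag_design")) {
    list(type = "tag_design", n_epitopes = x$n_epitopes,
         epitope_aa = x$epitope_aa, placement = x$placement,
         length_nt = x$length_nt, front_len_aa = x$front_len_aa,
         back_len_aa = x$back_len_aa, epitopes = x$epitopes, dead = x$dead)
  } else stopf("construct_json: unsupported class")
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
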