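# First-listed codon per amino acid in the standard genetic code;
# deterministic back-translation keeps embedding oracles exact.
.codon_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(gc)
  stats::setNames(names(gc)[match(aas, gc)], aas)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate a genome fixture by embedding back-translated proteins
#'
#' Each protein is back-translated (first-listed codon per amino acid,
#' standard code), flanked by in-frame stop codons, embedded in random
#' intergenic DNA on one contig, and placed on the forward or reverse
#' strand. With probability `noise$p_nrun` a run of `noise$n_run_len`
#' 'N' bases replaces whole codons mid-protein, so that translation
#' yields an internal 'X' run (one 'X' per replaced codon) exercising
#' the X-splitting rule downstream.
#'
#' @param proteome Tibble with `id`, `residues` (standard amino acids).
#' @param noise List with `p_nrun` (probability of an N-run per protein,
#'   default 0) and `n_run_len` (run length in nucleotides, default 30;
#'   an X-run of length k requires 3k embedded N nucleotides).
#' @param seed Integer seed.
#' @return List with `contigs` (tibble: id, bases) and `embedding`
#'   (tibble: contig, frame, start, end, protein_id, n_codons_masked;
#'   coordinates 0-based half-open on the forward strand, spanning the
#'   coding stretch between the flanking stops).
#' @export
generate_genome_fixture <- function(proteome, noise = list(), seed = 1) {
  noise <- utils::modifyList(list(p_nrun = 0, n_run_len = 30L), noise)
  codons <- .codon_for()
  with_substream(seed, "genome", {
    if (nrow(proteome) == 0) {
      contigs <- tibble(id = paste0("ctg", 1:3),
                        bases = map_chr(1:3, ~ random_dna(300)))
      return(list(contigs = contigs,
                  embedding = tibble(contig = character(), frame = integer(),
                                     start = integer(), end = integer(),
                                     protein_id = character(),
                                     n_codons_masked = integer())))
    }
    bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), proteome$residues)
    if (any(bad)) abort("proteome must contain standard amino acids only")
    rows <- pmap(list(proteome$id, proteome$residues, seq_len(nrow(proteome))),
                 function(pid, res, i) {
      aa <- strsplit(res, "")[[1]]
      cds <- codons[aa]
      n_masked <- 0L
      if (stats::runif(1) < noise$p_nrun && length(cds) > 4) {
        n_codons <- as.integer(ceiling(noise$n_run_len / 3))
        n_codons <- min(n_codons, length(cds) - 2L)
        at <- sample.int(length(cds) - n_codons - 1L, 1) + 1L
        cds[at:(at + n_codons - 1L)] <- "NNN"
        n_masked <- n_codons
      }
      left_pad <- sample(30:90, 1)
      right_pad <- sample(30:90, 1)
      fwd <- paste0(random_dna(left_pad), "TAA",
                    paste(cds, collapse = ""), "TGA", random_dna(right_pad))
      start <- left_pad + 3L                       # 0-based start of CDS
      end <- start + 3L * length(cds)
      len <- nchar(fwd)
      if (stats::runif(1) < 0.5) {
        frame <- (start %% 3L) + 1L
        bases <- fwd
      } else {
        bases <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
        new_start <- len - end
        new_end <- len - start
        start <- new_start; end <- new_end
        frame <- -(((len - end) %% 3L) + 1L)
      }
      list(contig = tibble(id = paste0("ctg", i), bases = bases),
           emb = tibble(contig = paste0("ctg", i), frame = frame,
                        start = as.integer(start), end = as.integer(end),
                        protein_id = pid, n_codons_masked = n_masked))
    })
    list(contigs = bind_rows(map(rows, "contig")),
         embedding = bind_rows(map(rows, "emb")))
  })
}
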