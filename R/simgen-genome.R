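# Synthetic genomic context: a random genome carrying convergent gene pairs
# whose intergenic gaps play the role of candidate safe sites, plus a planted
# CAST target (2-nt 5'-CN-3' PAM followed by a 32-nt protospacer).
# Coordinates are 0-based half-open throughout.

#' Generate a synthetic genome with convergent-gene intergenic regions
#'
#' Lays out `n_converging_pairs` pairs of convergent genes (`+` gene, gap,
#' `-` gene) separated by gene-free spacers on a random background sequence.
#' The gaps are the candidate safe sites consumed by [find_safe_sites()] and
#' [plant_target()].
#'
#' @param length Genome length in bp (>= 10000).
#' @param n_converging_pairs Number of convergent gene pairs to place.
#' @param intergenic_length_range Length range (min, max) of each convergent
#'   gap, in nt; must lie within `[50, 5000]`.
#' @param gene_length_range Length range of each gene body.
#' @param spacer_range Length range of the gene-free spacer between pairs.
#' @param mask_spec Optional named list of mask tables
#'   (`tibble(start, end)`, 0-based half-open), e.g.
#'   `list(ncRNA = ..., terminator = ...)`; validated and carried through.
#' @param seed Integer seed; fixed seed gives a byte-identical genome.
#' @return A `cast_genome`: list with `sequence`, `genes`
#'   (`gene`, `start`, `end`, `strand`), `intergenic` (one row per convergent
#'   gap), `masks` (`label`, `start`, `end`) and `length`.
#' @export
make_genome <- function(length = 50000, n_converging_pairs = 4,
                        intergenic_length_range = c(300, 600),
                        gene_length_range = c(600, 1200),
                        spacer_range = c(800, 2000),
                        mask_spec = NULL, seed = NULL) {
  stopifnot(length >= 10000)
  if (intergenic_length_range[1] < 50 || intergenic_length_range[2] > 5000 ||
      diff(intergenic_length_range) < 0) {
    abort("intergenic_length_range must be increasing and within [50, 5000]")
  }
  worst <- n_converging_pairs * (2 * gene_length_range[2] +
                                 intergenic_length_range[2] + spacer_range[2]) +
           spacer_range[2]
  if (worst > length) {
    abort(sprintf(
      "infeasible configuration: %d convergent pairs need up to %d bp but the genome is %d bp",
      n_converging_pairs, worst, length))
  }
  with_seed(seed, {
    seq <- random_dna(length)
    genes <- list(); inter <- list()
    pos <- round(runif(1, spacer_range[1], spacer_range[2]))
    for (i in seq_len(n_converging_pairs)) {
      la <- round(runif(1, gene_length_range[1], gene_length_range[2]))
      gap <- round(runif(1, intergenic_length_range[1], intergenic_length_range[2]))
      lb <- round(runif(1, gene_length_range[1], gene_length_range[2]))
      ga <- sprintf("g%03da", i); gb <- sprintf("g%03db", i)
      genes[[2 * i - 1]] <- tibble(gene = ga, start = pos, end = pos + la, strand = "+")
      inter[[i]] <- tibble(site = i, start = pos + la, end = pos + la + gap,
                           left_gene = ga, right_gene = gb, length = gap)
      genes[[2 * i]] <- tibble(gene = gb, start = pos + la + gap,
                               end = pos + la + gap + lb, strand = "-")
      pos <- pos + la + gap + lb + round(runif(1, spacer_range[1], spacer_range[2]))
    }
    masks <- validate_masks(mask_spec, length)
    structure(list(sequence = seq, genes = bind_rows(genes),
                   intergenic = bind_rows(inter), masks = masks,
                   length = length),
              class = "cast_genome")
  })
}

validate_masks <- function(mask_spec, genome_length) {
  if (is.null(mask_spec) || length(mask_spec) == 0) {
    return(tibble(label = character(), start = integer(), end = integer()))
  }
  out <- bind_rows(lapply(names(mask_spec), function(lab) {
    m <- as_tibble(mask_spec[[lab]])
    stopifnot(all(c("start", "end") %in% names(m)))
    tibble(label = lab, start = as.integer(m$start), end = as.integer(m$end))
  }))
  if (any(out$start < 0 | out$end > genome_length | out$start >= out$end)) {
    abort("mask intervals must be non-empty and within genome bounds")
  }
  out
}

#' @export
print.cast_genome <- function(x, ...) {
  cat(sprintf("<cast_genome> %d bp, %d genes, %d convergent intergenic regions, %d mask intervals\n",
              x$length, nrow(x$genes), nrow(x$intergenic), nrow(x$masks)))
  invisible(x)
}

#' Plant a CAST target (PAM + protospacer) in an intergenic region
#'
#' Writes a 2-nt 5'-CN-3' PAM immediately followed by a 32-nt protospacer with
#' GC content in `[40, 60]`% into the chosen convergent intergenic region,
#' oriented so that integration (a configurable offset downstream of the
#' protospacer 3' end) stays inside the region.
#'
#' @param genome A `cast_genome`.
#' @param site_index Which convergent intergenic region (row of
#'   `genome$intergenic`) hosts the target.
#' @param insertion_offset Expected integration distance downstream of the
#'   protospacer 3' end, used only to check the region is long enough.
#' @param margin Bases kept between the region start and the PAM.
#' @param seed Integer seed for the protospacer sequence.
#' @return List with the updated `genome` and `target`, a `cast_target`:
#'   `protospacer` (32 nt), `pam` (2 nt), `strand` (`"+"`),
#'   `pam_start`, `proto_start`, `proto_end` (0-based half-open) and
#'   `proto3p` (0-based coordinate of the protospacer's 3'-most base).
#' @export
plant_target <- function(genome, site_index = 1, insertion_offset = 49,
                         margin = 10, seed = NULL) {
  stopifnot(inherits(genome, "cast_genome"))
  if (!site_index %in% genome$intergenic$site) {
    abort("site_index does not name a planted intergenic region")
  }
  region <- genome$intergenic[genome$intergenic$site == site_index, ]
  need <- margin + 2 + 32 + insertion_offset + margin
  if (region$length < need) {
    abort(sprintf("region of %d nt is too short to host PAM + protospacer + %d bp offset",
                  region$length, insertion_offset))
  }
  with_seed(seed, {
    n_gc <- sample(13:19, 1) # 32-nt guide, GC in [40.6, 59.4]%
    bases <- sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
                      sample(c("A", "T"), 32 - n_gc, replace = TRUE)))
    proto <- paste(bases, collapse = "")
    pam <- paste0("C", sample(c("A", "C", "G", "T"), 1))
    pam_start <- region$start + margin
    seq <- genome$sequence
    substr(seq, pam_start + 1, pam_start + 34) <- paste0(pam, proto)
    genome$sequence <- seq
    target <- structure(list(protospacer = proto, pam = pam, strand = "+",
                             pam_start = pam_start,
                             proto_start = pam_start + 2L,
                             proto_end = pam_start + 34L,
                             proto3p = pam_start + 33L,
                             site_index = site_index),
                        class = "cast_target")
    list(genome = genome, target = target)
  })
}

#' Build a synthetic CAST delivery vector
#'
#' The vector carries the mini-transposon (left end, cargo, right end) plus a
#' plasmid backbone. Simple insertions integrate the transposon only;
#' cointegrates integrate the whole vector with a duplicated transposon
#' flanking the backbone.
#'
#' @param cargo_len,backbone_len,left_end_len,right_end_len Segment lengths, bp.
#' @param seed Integer seed.
#' @return A `cast_vector`: list with `transposon` (left end + cargo + right
#'   end sequence), `backbone` sequence, and 0-based half-open intervals
#'   `left_end`, `cargo`, `right_end` on the transposon.
#' @export
make_cast_vector <- function(cargo_len = 2000, backbone_len = 3000,
                             left_end_len = 150, right_end_len = 200,
                             seed = NULL) {
  with_seed(seed, {
    tn <- random_dna(left_end_len + cargo_len + right_end_len)
    structure(list(
      transposon = tn,
      backbone = random_dna(backbone_len),
      left_end = c(0L, as.integer(left_end_len)),
      cargo = c(as.integer(left_end_len), as.integer(left_end_len + cargo_len)),
      right_end = c(as.integer(left_end_len + cargo_len),
                    as.integer(left_end_len + cargo_len + right_end_len))
    ), class = "cast_vector")
  })
}

#' @export
print.cast_vector <- function(x, ...) {
  cat(sprintf("<cast_vector> transposon %d bp (L %d / cargo %d / R %d), backbone %d bp\n",
              nchar(x$transposon), diff(x$left_end),
              diff(x$cargo), diff(x$right_end), nchar(x$backbone)))
  invisible(x)
}
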