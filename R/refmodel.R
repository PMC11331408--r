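#' Target-site model for the 28S rDNA insertion locus
#'
#' Defines the coordinate frame shared by the allele simulator and the
#' junction caller. The first-strand nick on the rDNA scaffold is junction
#' coordinate 0: position 0 is the first scaffold base 3' of the nick on the
#' top (rRNA-sense) strand, and upstream positions are negative. The
#' second-strand nick sits `second_strand_offset` nt upstream (default 2 nt,
#' the offset characterised for ZoAl R2p).
#'
#' @param scaffold_seq rDNA scaffold sequence (top strand, A/C/G/T). A real
#'   consensus scaffold or a synthetic stand-in are equally valid.
#' @param nick_coord Number of scaffold bases 5' of the first-strand nick,
#'   i.e. the length of `upstream_seq`. Must be strictly inside the scaffold.
#' @param second_strand_offset Non-negative upstream offset (nt) of the
#'   second-strand nick.
#' @param scaffold_id Identifier for the scaffold.
#' @return An object of class `target_site` with fields `scaffold_id`,
#'   `scaffold_seq`, `nick_coord`, `second_strand_offset`, `upstream_seq`,
#'   `downstream_seq`.
#' @examples
#' site <- target_site("ACGTACGT", nick_coord = 4)
#' site$upstream_seq    # "ACGT"
#' site$downstream_seq  # "ACGT"
#' @export
target_site <- function(scaffold_seq, nick_coord, second_strand_offset = 2L,
                        scaffold_id = "rdna_scaffold") {
  check_dna(scaffold_seq, "scaffold_seq")
  n <- nchar(scaffold_seq)
  if (!is.numeric(nick_coord) || nick_coord <= 0 || nick_coord >= n) {
    abort("nick_coord must lie strictly inside the scaffold (0 < nick_coord < length)")
  }
  if (second_strand_offset < 0) abort("second_strand_offset must be >= 0")
  nick_coord <- as.integer(nick_coord)
  structure(
    list(
      scaffold_id = scaffold_id,
      scaffold_seq = scaffold_seq,
      nick_coord = nick_coord,
      second_strand_offset = as.integer(second_strand_offset),
      upstream_seq = substr(scaffold_seq, 1L, nick_coord),
      downstream_seq = substr(scaffold_seq, nick_coord + 1L, n)
    ),
    class = "target_site"
  )
}

#' @export
print.target_site <- function(x, ...) {
  cat("<target_site> ", x$scaffold_id, "\n", sep = "")
  cat("  scaffold: ", nchar(x$scaffold_seq), " nt; first-strand nick after position ",
      x$nick_coord, "\n", sep = "")
  cat("  second-strand nick offset: ", x$second_strand_offset, " nt upstream\n", sep = "")
  invisible(x)
}

#' Convert between scaffold positions and junction coordinates
#'
#' Junction coordinates are signed integers with 0 at the first base 3' of
#' the first-strand nick; scaffold positions are 1-based.
#'
#' @param site A [target_site()].
#' @param pos Integer vector of 1-based scaffold positions.
#' @param coord Integer vector of signed junction coordinates.
#' @return Integer vector of coordinates (resp. positions).
#' @export
junction_coord <- function(site, pos) {
  as.integer(pos) - site$nick_coord - 1L
}

#' @rdname junction_coord
#' @export
scaffold_pos <- function(site, coord) {
  as.integer(coord) + site$nick_coord + 1L
}

#' 5' module of an RNA insertion template
#'
#' The 5' module is the template region generated by ribozyme self-cleavage:
#' its first `rrna_homology_len` (h) bases are the rRNA sequence immediately
#' 5' of the first-strand nick (so the cDNA 3' end can anneal to the upstream
#' target site), followed by the module body. Modules with h = 0 (e.g. an
#' HDV genomic ribozyme module) carry no rRNA homology and force end-joining
#' at the 5' junction. Modules are treated as opaque sequences with an
#' annotated homology length; no folding is modelled.
#'
#' @param name Module name (e.g. "Rz-28", "gRz-like").
#' @param body_seq Module sequence 3' of the retained rRNA (DNA sense of the
#'   template top strand).
#' @param rrna_homology_len Retained rRNA length h (nt); 0 for homology-free
#'   modules.
#' @param site A [target_site()]; required when h > 0 to derive the rRNA
#'   prefix.
#' @param cleavage_pos Signed self-cleavage position relative to the nick;
#'   defaults to -h.
#' @param leader_retained Whether an uncleaved leader remains (default FALSE).
#' @return An object of class `five_prime_module` with fields `name`, `seq`,
#'   `rrna_homology_len`, `cleavage_pos`, `leader_retained`.
#' @export
five_prime_module <- function(name, body_seq, rrna_homology_len = 0L,
                              site = NULL, cleavage_pos = NULL,
                              leader_retained = FALSE) {
  check_dna(body_seq, "body_seq")
  h <- as.integer(rrna_homology_len)
  if (h < 0) abort("rrna_homology_len must be >= 0")
  prefix <- ""
  if (h > 0L) {
    if (is.null(site)) abort("site is required when rrna_homology_len > 0")
    if (h > nchar(site$upstream_seq)) abort("rrna_homology_len exceeds upstream scaffold")
    up <- site$upstream_seq
    prefix <- substr(up, nchar(up) - h + 1L, nchar(up))
  }
  structure(
    list(
      name = name,
      seq = paste0(prefix, body_seq),
      rrna_homology_len = h,
      cleavage_pos = as.integer(cleavage_pos %||% -h),
      leader_retained = isTRUE(leader_retained)
    ),
    class = "five_prime_module"
  )
}

#' Transgene RNA template (DNA sense)
#'
#' Assembles the full template in 5'->3' order: 5' module, optional cassette
#' body, 3' module, and tail. The default tail is 4 nt of downstream rRNA
#' (R4) followed by a 22-nt polyadenosine tract (A22). Template coordinate 1
#' is the template 5' terminus (= the cDNA 3' terminus); the rRNA homology
#' region, when present, occupies template positions 1..h.
#'
#' @param five_prime_module A [five_prime_module()].
#' @param three_prime_seq 3' module sequence (e.g. the terminal 98 nt of the
#'   GeFo 3' UTR).
#' @param site A [target_site()]; used to validate the module homology and to
#'   derive the default tail.
#' @param body_seq Optional cassette body between the modules (default "").
#' @param tail_seq 3' tail; default `R4 + A22` derived from `site`.
#' @param name Template name.
#' @return An object of class `transgene_template` with fields `name`,
#'   `module`, `body_seq`, `three_prime_seq`, `tail_seq`, `full_seq`,
#'   `homology_len`.
#' @export
transgene_template <- function(five_prime_module, three_prime_seq, site,
                               body_seq = "", tail_seq = NULL,
                               name = five_prime_module$name) {
  if (!inherits(five_prime_module, "five_prime_module")) {
    abort("five_prime_module must be a five_prime_module object")
  }
  check_dna(three_prime_seq, "three_prime_seq")
  if (nchar(body_seq) > 0) check_dna(body_seq, "body_seq")
  if (is.null(tail_seq)) {
    tail_seq <- paste0(substr(site$downstream_seq, 1L, 4L), strrep("A", 22L))
  }
  check_dna(tail_seq, "tail_seq")
  h <- five_prime_module$rrna_homology_len
  if (h > 0L) {
    up <- site$upstream_seq
    expected <- substr(up, nchar(up) - h + 1L, nchar(up))
    got <- substr(five_prime_module$seq, 1L, h)
    if (got != expected) {
      ev <- strsplit(expected, "")[[1L]]
      gv <- strsplit(got, "")[[1L]]
      off <- which(ev != gv)[1L]
      abort(sprintf(
        "module homology mismatch vs target site at template offset %d ('%s' vs rRNA '%s')",
        off, gv[off], ev[off]))
    }
  }
  full_seq <- paste0(five_prime_module$seq, body_seq, three_prime_seq, tail_seq)
  structure(
    list(
      name = name,
      module = five_prime_module,
      body_seq = body_seq,
      three_prime_seq = three_prime_seq,
      tail_seq = tail_seq,
      full_seq = full_seq,
      homology_len = h
    ),
    class = "transgene_template"
  )
}

#' @export
print.transgene_template <- function(x, ...) {
  cat("<transgene_template> ", x$name, "\n", sep = "")
  cat("  module ", x$module$name, " (", nchar(x$module$seq), " nt, h = ",
      x$homology_len, "); body ", nchar(x$body_seq), " nt; 3' module ",
      nchar(x$three_prime_seq), " nt; tail ", nchar(x$tail_seq), " nt\n", sep = "")
  cat("  full template: ", nchar(x$full_seq), " nt\n", sep = "")
  invisible(x)
}

#' Mapping references for the hierarchical alignment cascade
#'
#' Builds the composite `junction_ref` — rDNA flank, the template as inserted
#' by a seamless full-length anneal event (one copy of the homology region),
#' rDNA flank — plus the rDNA scaffold, an optional host reference and an
#' optional contaminant panel. `junction_ref` positions convert unambiguously
#' to either an rDNA junction coordinate or a template coordinate outside the
#' homology region.
#'
#' @param site A [target_site()].
#' @param template A [transgene_template()].
#' @param flank_len rDNA flank length on each side of the insertion
#'   (default 840). Must be at most the available scaffold flank and should
#'   exceed the read length.
#' @param host_ref Host genome sequence or synthetic decoy ("" to disable).
#' @param contaminants Named character vector of contaminant sequences
#'   (empty to make the contaminant screen a no-op).
#' @return An object of class `mapping_refs` with fields `junction_ref`,
#'   `rdna_ref`, `host_ref`, `contaminants`, `flank_len`, plus the boundary
#'   bookkeeping used by the caller (`insert_start`, `insert_end` 1-based
#'   positions of the inserted template portion within `junction_ref`).
#' @examples
#' site <- target_site(random_dna(2000), nick_coord = 1000)
#' mod <- five_prime_module("h11", random_dna(30), rrna_homology_len = 11, site = site)
#' tpl <- transgene_template(mod, three_prime_seq = random_dna(98), site = site)
#' refs <- mapping_references(site, tpl, flank_len = 400)
#' @export
mapping_references <- function(site, template, flank_len = 840L,
                               host_ref = "", contaminants = character()) {
  flank_len <- as.integer(flank_len)
  up_avail <- site$nick_coord
  down_avail <- nchar(site$scaffold_seq) - site$nick_coord
  if (flank_len > up_avail || flank_len > down_avail) {
    abort(sprintf("flank_len %d exceeds available scaffold flank (%d up / %d down)",
                  flank_len, up_avail, down_avail))
  }
  h <- template$homology_len
  L <- nchar(template$full_seq)
  up_flank <- substr(site$scaffold_seq, site$nick_coord - flank_len + 1L, site$nick_coord)
  down_flank <- substr(site$scaffold_seq, site$nick_coord + 1L, site$nick_coord + flank_len)
  inserted <- substr(template$full_seq, h + 1L, L)  # anneal form: one homology copy
  junction_ref <- paste0(up_flank, inserted, down_flank)
  structure(
    list(
      junction_ref = junction_ref,
      rdna_ref = site$scaffold_seq,
      host_ref = host_ref,
      contaminants = contaminants,
      flank_len = flank_len,
      insert_start = flank_len + 1L,
      insert_end = flank_len + nchar(inserted),
      homology_len = h,
      template_len = L,
      site = site,
      template = template
    ),
    class = "mapping_refs"
  )
}

#' @export
print.mapping_refs <- function(x, ...) {
  cat("<mapping_refs>\n")
  cat("  junction_ref: ", nchar(x$junction_ref), " nt (flanks ", x$flank_len,
      " nt; inserted template ", x$insert_end - x$insert_start + 1L, " nt)\n", sep = "")
  cat("  rdna_ref: ", nchar(x$rdna_ref), " nt; host_ref: ", nchar(x$host_ref),
      " nt; contaminants: ", length(x$contaminants), "\n", sep = "")
  invisible(x)
}

# Map a 1-based junction_ref position to a context annotation.
# Returns list(context, coord): context one of "rdna_up", "template",
# "rdna_down"; coord is a junction coordinate for rdna contexts and a
# 1-based template position for the template context.
junction_ref_context <- function(refs, pos) {
  f <- refs$flank_len
  if (pos <= f) {
    list(context = "rdna_up", coord = pos - f - 1L)
  } else if (pos <= refs$insert_end) {
    list(context = "template", coord = pos - f + refs$homology_len)
  } else {
    list(context = "rdna_down", coord = pos - refs$insert_end - 1L)
  }
}

#' Write reference sequences to FASTA
#'
#' @param refs A [mapping_references()] object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_refs_fasta <- function(refs, path) {
  seqs <- c(junction_ref = refs$junction_ref, rdna = refs$rdna_ref)
  if (nchar(refs$host_ref) > 0) seqs <- c(seqs, host = refs$host_ref)
  if (length(refs$contaminants) > 0) {
    nm <- names(refs$contaminants) %||% paste0("contaminant", seq_along(refs$contaminants))
    seqs <- c(seqs, setNames(unname(refs$contaminants), paste0("contam_", nm)))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Describe reference-model objects as JSON
#'
#' @param site A [target_site()].
#' @param template A [transgene_template()].
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
refmodel_json <- function(site, template, path = NULL) {
  desc <- list(
    target_site = list(
      scaffold_id = site$scaffold_id,
      scaffold_len = nchar(site$scaffold_seq),
      nick_coord = site$nick_coord,
      second_strand_offset = site$second_strand_offset
    ),
    template = list(
      name = template$name,
      module = template$module$name,
      rrna_homology_len = template$homology_len,
      cleavage_pos = template$module$cleavage_pos,
      module_len = nchar(template$module$seq),
      body_len = nchar(template$body_seq),
      three_prime_len = nchar(template$three_prime_seq),
      tail_len = nchar(template$tail_seq),
      full_len = nchar(template$full_seq)
    )
  )
  js <- jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
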