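#' Domain map of the CaMKII-alpha subunit
#'
#' Named, ordered, disjoint residue ranges (1-based, inclusive) partitioning
#' the analyzed subunit span into the four classic CaMKII subdomains: the
#' N-terminal kinase domain, the regulatory segment (carrying T286), the
#' variable linker, and the C-terminal hub (association) domain.
#'
#' The default boundaries (kinase 1-274, regulatory 275-314, linker 315-343,
#' hub 344-478) place the frequently crosslinked lysines 344 and 347 in the
#' hub, consistent with their description as a hub-hub contact.  All
#' boundaries are overridable.
#'
#' @param kinase,regulatory,linker,hub integer length-2 vectors
#'   `c(start, end)`, 1-based inclusive.
#' @return an object of class `domain_map`: a named list of ranges.
#' @examples
#' dm <- domain_map()
#' classify_domain(100, dm)  # "kinase"
#' classify_domain(344, dm)  # "hub"
#' @export
domain_map <- function(kinase = c(1L, 274L),
                       regulatory = c(275L, 314L),
                       linker = c(315L, 343L),
                       hub = c(344L, 478L)) {
  ranges <- list(kinase = as.integer(kinase), regulatory = as.integer(regulatory),
                 linker = as.integer(linker), hub = as.integer(hub))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      abort_validation(sprintf("domain '%s' must be c(start, end) with 1 <= start <= end", nm))
    }
  }
  # disjoint, ordered, contiguous coverage of the span
  starts <- vapply(ranges, `[`, integer(1), 1L)
  ends <- vapply(ranges, `[`, integer(1), 2L)
  if (any(diff(starts) <= 0) || any(starts[-1] != ends[-length(ends)] + 1L)) {
    abort_validation("domain ranges must be ordered, disjoint and jointly cover the span")
  }
  structure(ranges, class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat("CaMKII subunit domain map (1-based residue ranges)\n")
  for (nm in names(x)) cat(sprintf("  %-10s %4d-%4d\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' Domain names of a domain map
#' @param map a [domain_map()].
#' @return character vector of domain names in sequence order.
#' @export
domain_names <- function(map) names(unclass(map))

#' Total span covered by a domain map
#' @param map a [domain_map()].
#' @return integer `c(start, end)`.
#' @export
domain_span <- function(map) {
  r <- unclass(map)
  c(r[[1]][1], r[[length(r)]][2])
}

#' Synthetic CaMKII-alpha-like subunit sequence
#'
#' A 478-residue SYNTHETIC stand-in sequence used by the crosslink generator
#' to sample amine-reactive (lysine) crosslink sites with a realistic
#' domain-resolved distribution.  It is NOT the curated UniProt Q9UQM7 entry:
#' it reproduces only the features the generator needs -- the subunit length,
#' the default domain boundaries, tryptic cleavage sites, and lysines placed
#' within each domain (including lysines at positions 42, 344 and 347, which
#' are genuine CaMKII-alpha lysine positions).  Mass and nitrogen arithmetic
#' elsewhere in the package operates on whatever peptide sequences it is
#' given and does not depend on this stand-in.
#'
#' @return a single uppercase character string of length 478.
#' @export
synthetic_camk2a_sequence <- function() {
  # deterministic background: cycle of non-K residues with R providing extra
  # tryptic sites; lysines overlaid at fixed per-domain positions
  background <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P",
                  "Q", "R", "S", "T", "V", "W", "Y", "G", "A", "L")
  seq_chr <- background[((seq_len(478L) - 1L) %% length(background)) + 1L]
  lys <- c(
    21L, 42L, 56L, 75L, 92L, 110L, 137L, 148L, 166L, 190L, 210L, 235L, 250L, 267L, # kinase
    280L, 291L, 300L, 307L,                                                        # regulatory
    320L, 330L, 338L,                                                              # linker
    344L, 347L, 360L, 381L, 402L, 430L, 456L, 470L                                 # hub
  )
  seq_chr[lys] <- "K"
  paste(seq_chr, collapse = "")
}

#' Lysine positions of a sequence, optionally restricted to a domain
#'
#' @param sequence uppercase one-letter protein sequence.
#' @param map a [domain_map()]; optional.
#' @param domain domain name to restrict to; `NULL` for the whole covered span.
#' @return integer vector of 1-based lysine positions.
#' @export
lysine_positions <- function(sequence, map = domain_map(), domain = NULL) {
  pos <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == "K")
  if (!is.null(domain)) {
    r <- unclass(map)[[domain]]
    if (is.null(r)) abort_validation(sprintf("unknown domain '%s'", domain))
    pos <- pos[pos >= r[1] & pos <= r[2]]
  }
  pos
}

#' Tryptic-style peptide containing a given residue
#'
#' Extracts the peptide spanning from the residue after the preceding K/R to
#' the next K/R at or after `pos` (one missed cleavage at the crosslinked
#' lysine itself is implicit: a DSS-modified lysine is not cleaved, so the
#' peptide extends through it to the following K/R).
#'
#' @param sequence protein sequence.
#' @param pos 1-based residue position contained in the peptide.
#' @return list with `peptide` (string), `start`, `end` (1-based positions).
#' @export
tryptic_peptide_at <- function(sequence, pos) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (pos < 1L || pos > n) abort_validation("pos outside sequence")
  cleav <- which(chars %in% c("K", "R"))
  prev <- cleav[cleav < pos]
  start <- if (length(prev)) max(prev) + 1L else 1L
  nxt <- cleav[cleav > pos]
  end <- if (length(nxt)) min(nxt) else n
  list(peptide = paste(chars[start:end], collapse = ""), start = start, end = end)
}
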