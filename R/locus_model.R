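#' Load an ordinal topology model of a TR locus
#'
#' Returns the packaged gene-order table for one species and locus. Each
#' gene segment carries an ordinal position (strictly increasing 5' to 3'),
#' its transcriptional orientation, segment class (V/D/J/C), D-J-C cluster
#' membership for TRB, recombination-signal-sequence (RSS) spacer classes on
#' each flank, and an IMGT-style functionality label. Ordinals, not base-pair
#' coordinates, are stored: mechanism inference needs only relative order.
#' All structural invariants (ordinal monotonicity, a single reverse V at the
#' 3' end of TRB, canonical RSS spacer classes per segment class) are
#' validated at load time.
#'
#' @param species `"human"`, `"mouse"`, or `"toy"` (a reduced locus used by
#'   the excision-oracle tests).
#' @param locus `"TRA"` or `"TRB"`.
#' @return a `locus_map`: list with `species`, `locus`, `genes` (the ordered
#'   data frame) and `index` (name -> row lookup).
#' @examples
#' trb <- load_locus("human", "TRB")
#' subset(trb$genes, orientation == "reverse")$name  # "TRBV30"
#' @export
load_locus <- function(species = c("human", "mouse", "toy"),
                       locus = c("TRA", "TRB")) {
  species <- match.arg(species)
  locus <- match.arg(locus)
  path <- system.file("extdata", "locus",
                      sprintf("%s_%s.tsv", species, locus),
                      package = "tcrtrace")
  if (!nzchar(path)) stop("no packaged locus table for ", species, " ", locus)
  genes <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_locus(genes, species, locus)
  map <- list(species = species, locus = locus, genes = genes,
              index = stats::setNames(seq_len(nrow(genes)), genes$name))
  class(map) <- "locus_map"
  map
}

validate_locus <- function(genes, species, locus) {
  need <- c("name", "species", "locus", "segment_class", "ordinal",
            "orientation", "cluster", "rss_5p", "rss_3p", "functionality")
  missing <- setdiff(need, names(genes))
  if (length(missing))
    stop("locus table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(genes$name))
    stop("locus table invariant violated: duplicate gene names")
  if (any(diff(genes$ordinal) <= 0))
    stop("locus table invariant violated: ordinals not strictly increasing")
  rev_v <- genes$name[genes$segment_class == "V" &
                        genes$orientation == "reverse"]
  if (locus == "TRB" && species != "toy") {
    expected_rev <- if (species == "human") "TRBV30" else "TRBV31"
    if (!identical(rev_v, expected_rev))
      stop("locus table invariant violated: TRB must contain exactly one ",
           "reverse-orientation V (", expected_rev, ")")
    # the reverse V lies 3' of the whole D-J-C region
    last_c <- max(genes$ordinal[genes$segment_class == "C"])
    if (genes$ordinal[genes$name == expected_rev] <= last_c)
      stop("locus table invariant violated: reverse V must lie 3' of ",
           "the D-J-C clusters")
    djc <- genes[genes$segment_class %in% c("D", "J", "C"), ]
    if (!all(djc$cluster %in% c("DJC1", "DJC2")))
      stop("locus table invariant violated: TRB D/J/C segments must ",
           "belong to a D-J-C cluster")
    o <- function(nm) genes$ordinal[genes$name == nm]
    c1 <- djc[djc$cluster == "DJC1", ]
    c2 <- djc[djc$cluster == "DJC2", ]
    if (!(max(c1$ordinal) < min(c2$ordinal)))
      stop("locus table invariant violated: DJC1 must precede DJC2")
  }
  if (locus == "TRA" && length(rev_v))
    stop("locus table invariant violated: TRA has no reverse V segments")
  ok_rss <- with(genes, switch_ok <- (
    (segment_class == "V" & rss_5p == "none" & rss_3p == "spacer23") |
    (segment_class == "D" & rss_5p == "spacer12" & rss_3p == "spacer23") |
    (segment_class == "J" & rss_5p == "spacer12" & rss_3p == "none") |
    (segment_class == "C" & rss_5p == "none" & rss_3p == "none")))
  if (!all(ok_rss))
    stop("locus table invariant violated: non-canonical RSS assignment for ",
         paste(genes$name[!ok_rss], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("<locus_map> %s %s: %d segments (%d V, %d D, %d J, %d C)\n",
              x$species, x$locus, nrow(x$genes),
              sum(x$genes$segment_class == "V"),
              sum(x$genes$segment_class == "D"),
              sum(x$genes$segment_class == "J"),
              sum(x$genes$segment_class == "C")))
  invisible(x)
}

#' Normalize a gene call against a locus map
#'
#' Strips allele suffixes (`"TRBV19*01"` -> `"TRBV19"`), maps dual-name
#' TRAV/DV genes to their TRAV alias (`"TRAV14/DV4"` -> `"TRAV14"`), and
#' resolves ambiguous multi-gene calls (`"TRBV12-3/12-4"`) to the 5'-most
#' member present in the map, with a warning.
#'
#' @param call raw gene call string.
#' @param map a `locus_map`.
#' @return normalized gene name (possibly `""` for an empty call).
#' @export
normalize_gene_call <- function(call, map) {
  if (is.na(call) || !nzchar(call)) return("")
  g <- sub("\\*.*$", "", trimws(call))
  if (g %in% names(map$index)) return(g)
  if (grepl("/DV", g, fixed = TRUE)) {
    g2 <- sub("/DV.*$", "", g)
    if (g2 %in% names(map$index)) return(g2)
  }
  if (grepl("/", g, fixed = TRUE)) {
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    prefix <- sub("([0-9].*)$", "", parts[1])
    cands <- c(parts[1], paste0(prefix, parts[-1]))
    cands <- cands[cands %in% names(map$index)]
    if (length(cands)) {
      pick <- cands[which.min(map$index[cands])]
      warning("ambiguous gene call '", call, "' resolved to 5'-most member ",
              pick)
      return(pick)
    }
  }
  g
}

locus_gene <- function(name, map) {
  i <- map$index[name]
  if (is.na(i)) stop("unknown gene '", name, "' in ", map$species, " ",
                     map$locus, " locus map")
  map$genes[i, ]
}

#' Is gene `a` 5' of gene `b`?
#'
#' @param a,b gene names present in `map`.
#' @param map a `locus_map`.
#' @return `TRUE` iff `a`'s ordinal is strictly less than `b`'s.
#' @export
upstream_of <- function(a, b, map) {
  locus_gene(a, map)$ordinal < locus_gene(b, map)$ordinal
}

#' Check the 12/23 recombination-signal rule for a join
#'
#' A join of segment `a`'s 3' flank to segment `b`'s 5' flank is allowed
#' iff one facing RSS has a 12-nt spacer and the other a 23-nt spacer.
#' Segments lacking the facing RSS (e.g. C genes) are never compatible.
#'
#' @param a,b rows of a locus table (as returned by indexing
#'   `map$genes`), or gene names to be looked up in `map`.
#' @param map a `locus_map` (required when `a`/`b` are names).
#' @param join join geometry; only `"a3_to_b5"` is defined.
#' @return logical.
#' @export
rss_compatible <- function(a, b, map = NULL, join = "a3_to_b5") {
  stopifnot(identical(join, "a3_to_b5"))
  if (is.character(a)) a <- locus_gene(a, map)
  if (is.character(b)) b <- locus_gene(b, map)
  s <- c(a$rss_3p, b$rss_5p)
  all(s %in% c("spacer12", "spacer23")) && s[1] != s[2]
}

#' Functional V gene names for a species
#'
#' Genes labelled `functional` in the packaged locus tables; ORF-class and
#' pseudogene-class segments are excluded (conservative: a chain using an
#' ORF V is called non-functional).
#'
#' @param species `"human"` or `"mouse"`.
#' @param locus `"TRA"`, `"TRB"`, or `"both"` (default).
#' @return character vector of gene names.
#' @export
functional_v_genes <- function(species, locus = "both") {
  loci <- if (locus == "both") c("TRA", "TRB") else locus
  unlist(lapply(loci, function(l) {
    g <- load_locus(species, l)$genes
    g$name[g$segment_class == "V" & g$functionality == "functional"]
  }), use.names = FALSE)
}
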