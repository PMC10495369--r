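#' Reporter ORF designs
#'
#' A reporter design describes the ORF layout of a single-molecule translation
#' reporter in codon units: where each fluorescent epitope of the (up to two)
#' antibody-binding cassettes is completed, where the insert (repeat or control
#' sequence) sits, and where ribosomes terminate depending on their reading
#' frame.  Positions are 1-based codon indices; one codon corresponds to one
#' amino acid (3 nt).
#'
#' Built-in presets:
#' \describe{
#'   \item{`elongation_GGGGCC70`}{One-color elongation reporter: a 24-epitope
#'     SunTag cassette (528 codons), a 140-codon repeat insert (420 nt of
#'     GGGGCC), and a 335-codon downstream flank (degron), 1003 codons in all
#'     (3009 nt ORF).}
#'   \item{`elongation_NLuc`}{Same backbone with the repeat replaced by a
#'     171-codon (513 nt) NanoLuc control insert; 1034 codons in all.}
#'   \item{`frameshift_twocolor`}{Two-color frameshift reporter: 24 channel-1
#'     (HA) epitopes upstream of a 140-codon repeat insert, stop codon for the
#'     upstream frame immediately after the insert, then a 24-epitope channel-2
#'     (SunTag) cassette reachable only by ribosomes that shift frame inside
#'     the insert (or by cap-independent initiation).}
#' }
#'
#' @param spec Preset name (see Details) or `"explicit"` to build a design from
#'   the remaining arguments.
#' @param name Label for an explicit design.
#' @param regions Data frame with columns `label`, `start`, `end`, `role`
#'   (one of `"epitope_cassette"`, `"insert"`, `"flank"`); regions must tile
#'   `1:total_length` without gaps or overlap.
#' @param epitope_positions_ch1,epitope_positions_ch2 Strictly increasing codon
#'   indices at which an epitope of the given channel is completed; each must
#'   lie inside an `epitope_cassette` region.  Channel 2 may be empty.
#' @param ch1_stop Codon at which a ribosome that never left the channel-1
#'   frame terminates.
#' @param ch2_reachable_only_by Character vector, subset of
#'   `c("frameshift", "ran_initiation", "in_frame")`.
#' @param total_length Total ORF length in codons.
#'
#' @return An object of class `reporter_design`.
#' @examples
#' d <- build_reporter("elongation_GGGGCC70")
#' insert_length(d)  # 140
#' @export
build_reporter <- function(spec = "elongation_GGGGCC70",
                           name = spec,
                           regions = NULL,
                           epitope_positions_ch1 = NULL,
                           epitope_positions_ch2 = integer(0),
                           ch1_stop = NULL,
                           ch2_reachable_only_by = character(0),
                           total_length = NULL) {
  if (spec != "explicit") {
    return(reporter_preset(spec))
  }
  design <- structure(list(
    name = name,
    total_length = as.integer(total_length),
    regions = as.data.frame(regions, stringsAsFactors = FALSE),
    epitope_positions_ch1 = as.integer(epitope_positions_ch1),
    epitope_positions_ch2 = as.integer(epitope_positions_ch2),
    ch1_stop = as.integer(ch1_stop),
    ch2_reachable_only_by = as.character(ch2_reachable_only_by)
  ), class = "reporter_design")
  validate_reporter(design)
}

reporter_preset <- function(spec) {
  # SunTag/HA cassettes are laid out as 24 epitopes completing every 22 codons
  # (cassette length 528); with a 140-codon repeat insert and a 335-codon
  # downstream flank this reproduces the printed construct sizes
  # (3009 nt ORF = 1003 codons, repeat 420 nt = 140 codons, NLuc 513 nt = 171).
  ep <- function(offset, n = 24L, every = 22L) offset + every * seq_len(n)
  switch(spec,
    elongation_GGGGCC70 = build_reporter(
      "explicit", name = "elongation_GGGGCC70",
      regions = data.frame(
        label = c("suntag", "repeat", "degron"),
        start = c(1L, 529L, 669L),
        end   = c(528L, 668L, 1003L),
        role  = c("epitope_cassette", "insert", "flank")),
      epitope_positions_ch1 = ep(0L),
      ch1_stop = 1003L,
      total_length = 1003L),
    elongation_NLuc = build_reporter(
      "explicit", name = "elongation_NLuc",
      regions = data.frame(
        label = c("suntag", "nluc", "degron"),
        start = c(1L, 529L, 700L),
        end   = c(528L, 699L, 1034L),
        role  = c("epitope_cassette", "insert", "flank")),
      epitope_positions_ch1 = ep(0L),
      ch1_stop = 1034L,
      total_length = 1034L),
    frameshift_twocolor = build_reporter(
      "explicit", name = "frameshift_twocolor",
      regions = data.frame(
        label = c("ha", "repeat", "suntag"),
        start = c(1L, 529L, 669L),
        end   = c(528L, 668L, 1196L),
        role  = c("epitope_cassette", "insert", "epitope_cassette")),
      epitope_positions_ch1 = ep(0L),
      epitope_positions_ch2 = ep(668L),
      ch1_stop = 668L,
      ch2_reachable_only_by = c("frameshift", "ran_initiation"),
      total_length = 1196L),
    stop("unknown reporter preset: ", spec)
  )
}

validate_reporter <- function(d) {
  r <- d$regions
  req <- c("label", "start", "end", "role")
  if (!all(req %in% names(r))) stop("regions must have columns label/start/end/role")
  if (any(!r$role %in% c("epitope_cassette", "insert", "flank")))
    stop("layout error: unknown region role")
  if (any(r$start < 1L) || any(r$end > d$total_length) || any(r$start > r$end))
    stop("layout error: region outside [1, total_length]")
  r <- r[order(r$start), ]
  if (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)] + 1L))
    stop("layout error: regions must tile [1, total_length] without overlap")
  if (r$start[1] != 1L || r$end[nrow(r)] != d$total_length)
    stop("layout error: regions must tile [1, total_length]")
  if (sum(r$role == "insert") > 1L) stop("layout error: more than one insert region")
  d$regions <- r

  in_cassette <- function(p) {
    any(r$role == "epitope_cassette" & r$start <= p & p <= r$end)
  }
  for (ch in c("epitope_positions_ch1", "epitope_positions_ch2")) {
    pos <- d[[ch]]
    if (length(pos)) {
      if (any(diff(pos) <= 0L)) stop("layout error: epitope positions must be strictly increasing")
      if (!all(vapply(pos, in_cassette, logical(1))))
        stop("layout error: epitope outside an epitope_cassette region")
    }
  }
  ins <- insert_region(d)
  if (length(d$epitope_positions_ch2) && !is.null(ins)) {
    if (any(d$epitope_positions_ch1 >= ins$start))
      stop("layout error: two-color design requires all ch1 epitopes upstream of the insert")
    if (any(d$epitope_positions_ch2 <= ins$end))
      stop("layout error: two-color design requires all ch2 epitopes downstream of the insert")
  }
  if (is.na(d$ch1_stop) || d$ch1_stop < 1L || d$ch1_stop > d$total_length)
    stop("layout error: ch1_stop outside ORF")
  d
}

#' Insert region of a design
#'
#' @param design A `reporter_design`.
#' @return For [insert_region()], a list with `start` and `end` codon (or
#'   `NULL` when the design has no insert); for [insert_length()], the insert
#'   length in codons (0 when absent).
#' @export
insert_region <- function(design) {
  i <- which(design$regions$role == "insert")
  if (!length(i)) return(NULL)
  list(start = design$regions$start[i], end = design$regions$end[i])
}

#' @rdname insert_region
#' @export
insert_length <- function(design) {
  ins <- insert_region(design)
  if (is.null(ins)) 0L else ins$end - ins$start + 1L
}

#' Flanking (non-insert) length of a design
#'
#' Total codons outside the insert; the quantity `L_0` of the runoff-time
#' decomposition.
#' @param design A `reporter_design`.
#' @return Length in codons.
#' @export
flank_length <- function(design) {
  design$total_length - insert_length(design)
}

#' @export
print.reporter_design <- function(x, ...) {
  cat("<reporter_design> ", x$name, ": ", x$total_length, " codons, insert ",
      insert_length(x), " codons, ", length(x$epitope_positions_ch1),
      " ch1 epitopes", sep = "")
  if (length(x$epitope_positions_ch2))
    cat(", ", length(x$epitope_positions_ch2), " ch2 epitopes", sep = "")
  cat("\n")
  invisible(x)
}
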