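# Categorical U-Net architecture space: connection patterns, filter counts,
# squeeze-and-excitation settings, and network depth.

#' Define the configurable U-Net search space
#'
#' The space is categorical and tree-structured.  Each encoder/decoder block
#' is described by a 4-bit connection pattern over the multi-branch module
#' (branches A1..A4; at least one active, so patterns 1..15), a filter count,
#' whether a squeeze-and-excitation (SE) block is appended, and - only when
#' it is - the SE reduction ratio.  Network depth (number of encoder/decoder
#' pairs) ranges over 1..5.  With the default candidate sets each block has
#' 15 x 6 x (1 + 4) = 450 configurations.
#'
#' @param patterns Integer vector of admissible connection patterns (subset
#'   of 1:15).  Bit i (most significant first in the bitstring form)
#'   activates branch Ai.
#' @param filters Integer vector of admissible filter counts.
#' @param se_ratios Integer vector of admissible SE reduction ratios.
#' @param se_allowed Logical; if `FALSE` the SE block is never enabled and
#'   each block has `length(patterns) * length(filters)` configurations.
#' @param depths Integer vector of admissible depths (subset of 1:5).  The
#'   canonical study configuration searches depths 2..5.
#' @return An object of class `unet_space`.
#' @examples
#' sp <- unet_space()
#' count_block_configs(sp)      # 450
#' format(count_search_space(sp))  # the exact 27-digit space size
#' @export
unet_space <- function(patterns = 1:15,
                       filters = c(8L, 16L, 32L, 64L, 128L, 256L),
                       se_ratios = c(2L, 4L, 8L, 16L),
                       se_allowed = TRUE,
                       depths = 2:5) {
  patterns <- sort(unique(as.integer(patterns)))
  filters <- sort(unique(as.integer(filters)))
  se_ratios <- sort(unique(as.integer(se_ratios)))
  depths <- sort(unique(as.integer(depths)))
  if (length(patterns) == 0 || any(patterns < 1L | patterns > 15L))
    stop("patterns must be a nonempty subset of 1:15")
  if (length(filters) == 0 || any(filters < 1L))
    stop("filters must be nonempty positive integers")
  if (se_allowed && length(se_ratios) == 0)
    stop("se_ratios must be nonempty when se_allowed")
  if (length(depths) == 0 || any(depths < 1L | depths > 5L))
    stop("depths must be a nonempty subset of 1:5")
  structure(list(patterns = patterns, filters = filters,
                 se_ratios = se_ratios, se_allowed = isTRUE(se_allowed),
                 depths = depths),
            class = "unet_space")
}

#' @export
print.unet_space <- function(x, ...) {
  cat("U-Net architecture space\n")
  cat("  connection patterns:", paste(pattern_to_bits(x$patterns), collapse = " "), "\n")
  cat("  filters:", paste(x$filters, collapse = " "), "\n")
  if (x$se_allowed)
    cat("  SE ratios:", paste(x$se_ratios, collapse = " "), "(or SE off)\n")
  else cat("  SE: disabled\n")
  cat("  depths:", paste(x$depths, collapse = " "), "\n")
  cat("  block configurations:", count_block_configs(x), "\n")
  cat("  architectures:", format(count_search_space(x)), "\n")
  invisible(x)
}

#' Convert connection patterns to/from 4-character bitstrings
#'
#' Pattern integers are read as the binary number `b1 b2 b3 b4` with branch
#' A1 the most significant bit, so `"0001"` is 1 and `"1111"` is 15.
#'
#' @param pattern Integer vector in 1..15.
#' @param bits Character vector of 4-character bitstrings.
#' @return `pattern_to_bits` returns bitstrings; `bits_to_pattern` returns
#'   integers.
#' @examples
#' pattern_to_bits(14)   # "1110"
#' bits_to_pattern("0001")
#' @export
pattern_to_bits <- function(pattern) {
  pattern <- as.integer(pattern)
  if (any(is.na(pattern) | pattern < 1L | pattern > 15L))
    stop("connection pattern must be in 1..15 (at least one branch active)")
  vapply(pattern, function(p) {
    paste(as.integer(bitwAnd(p, c(8L, 4L, 2L, 1L)) > 0L), collapse = "")
  }, character(1))
}

#' @rdname pattern_to_bits
#' @export
bits_to_pattern <- function(bits) {
  if (any(!grepl("^[01]{4}$", bits)))
    stop("connection pattern bitstring must be 4 characters of 0/1, got: ",
         paste(bits, collapse = ", "))
  p <- vapply(bits, function(b) {
    sum(as.integer(strsplit(b, "")[[1]]) * c(8L, 4L, 2L, 1L))
  }, numeric(1), USE.NAMES = FALSE)
  if (any(p < 1)) stop("connection pattern \"0000\" is invalid: at least one branch must be active")
  as.integer(p)
}

#' Active branches of a connection pattern
#' @param pattern Integer in 1..15.
#' @return Integer vector of active branch indices (subset of 1:4).
#' @keywords internal
pattern_branches <- function(pattern) {
  which(bitwAnd(as.integer(pattern), c(8L, 4L, 2L, 1L)) > 0L)
}

#' Construct one block configuration
#'
#' @param pattern Connection pattern, either an integer 1..15 or a 4-bit
#'   string such as `"1110"`.
#' @param filters Number of convolution filters in the block.
#' @param se Logical; append an SE block?
#' @param se_ratio SE reduction ratio; required iff `se` is `TRUE` and
#'   ignored (dropped) otherwise.
#' @return An object of class `block_config`.
#' @examples
#' block_config("1110", 128, se = TRUE, se_ratio = 16)
#' @export
block_config <- function(pattern, filters, se = FALSE, se_ratio = NULL) {
  if (is.character(pattern)) pattern <- bits_to_pattern(pattern)
  bc <- structure(list(pattern = as.integer(pattern),
                       filters = as.integer(filters),
                       se = isTRUE(se),
                       se_ratio = if (isTRUE(se)) as.integer(se_ratio) else NULL),
                  class = "block_config")
  validate_block_config(bc)
  bc
}

#' Validate a block configuration
#' @param bc A `block_config`.
#' @param space Optional `unet_space` whose candidate sets must contain the
#'   fields.
#' @return `bc`, invisibly; errors on violation.
#' @export
validate_block_config <- function(bc, space = NULL) {
  if (!inherits(bc, "block_config")) stop("not a block_config")
  if (length(bc$pattern) != 1L || is.na(bc$pattern) ||
      bc$pattern < 1L || bc$pattern > 15L)
    stop("connection pattern must be in 1..15")
  if (length(bc$filters) != 1L || is.na(bc$filters) || bc$filters < 1L)
    stop("filters must be a positive integer")
  if (bc$se) {
    if (is.null(bc$se_ratio) || length(bc$se_ratio) != 1L || is.na(bc$se_ratio) ||
        bc$se_ratio < 1L)
      stop("se_ratio must be a positive integer when the SE block is enabled")
  } else if (!is.null(bc$se_ratio)) {
    stop("se_ratio must be absent when the SE block is disabled")
  }
  if (!is.null(space)) {
    if (!(bc$pattern %in% space$patterns)) stop("pattern outside the space")
    if (!(bc$filters %in% space$filters)) stop("filters outside the space")
    if (bc$se && !space$se_allowed) stop("SE not allowed in this space")
    if (bc$se && !(bc$se_ratio %in% space$se_ratios)) stop("se_ratio outside the space")
  }
  invisible(bc)
}

#' Construct an architecture genotype
#'
#' A genotype is the discrete encoding of one candidate U-Net: the depth and
#' one `block_config` per encoder and decoder position.  Encoder 1 is the
#' shallowest (first applied); decoder 1 is the deepest (first applied).
#'
#' @param encoders,decoders Lists of `block_config`, one per position; both
#'   must have the same length (the depth, 1..5).
#' @return An object of class `unet_genotype`.
#' @export
genotype <- function(encoders, decoders) {
  g <- structure(list(depth = length(encoders),
                      encoders = encoders, decoders = decoders),
                 class = "unet_genotype")
  validate_genotype(g)
  g
}

#' Validate a genotype
#' @param g A `unet_genotype`.
#' @param space Optional `unet_space` constraining all fields.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_genotype <- function(g, space = NULL) {
  if (!inherits(g, "unet_genotype")) stop("not a unet_genotype")
  if (g$depth < 1L || g$depth > 5L) stop("depth must be in 1..5")
  if (length(g$encoders) != g$depth || length(g$decoders) != g$depth)
    stop("encoder and decoder lists must each have `depth` entries")
  for (bc in c(g$encoders, g$decoders)) validate_block_config(bc, space)
  if (!is.null(space) && !(g$depth %in% space$depths))
    stop("depth outside the space")
  invisible(g)
}

#' @export
print.unet_genotype <- function(x, ...) {
  fmt <- function(blocks) {
    vapply(blocks, function(b) {
      sprintf("%s f%-3d %s", pattern_to_bits(b$pattern), b$filters,
              if (b$se) sprintf("SE/%d", b$se_ratio) else "-")
    }, character(1))
  }
  cat(sprintf("U-Net genotype (depth %d)\n", x$depth))
  cat("  enc:", paste(fmt(x$encoders), collapse = " | "), "\n")
  cat("  dec:", paste(fmt(x$decoders), collapse = " | "), "\n")
  invisible(x)
}

#' Count distinct block configurations
#'
#' With SE allowed the count is
#' `|patterns| * |filters| * (1 + |se_ratios|)`: the `1` is the SE-off
#' option, under which the ratio is undefined.  The default space gives
#' 15 x 6 x (1 + 4) = 450.
#'
#' @param space A `unet_space`.
#' @param se_allowed Logical override of `space$se_allowed`.
#' @return Integer count.
#' @export
count_block_configs <- function(space = unet_space(), se_allowed = space$se_allowed) {
  se_opts <- if (se_allowed) 1L + length(space$se_ratios) else 1L
  length(space$patterns) * length(space$filters) * se_opts
}

#' Count the architecture search space exactly
#'
#' An architecture of depth d has 2d independent blocks, so the space size
#' is `sum_d B^(2d)` over the admissible depths, with B the per-block count.
#' The default space over depths 2..5 contains
#' 450^4 + 450^6 + 450^8 + 450^10, about 3.4e26 architectures; the count is
#' computed exactly in arbitrary precision.
#'
#' @param space A `unet_space`.
#' @param depths Depths to include; defaults to `space$depths`.  An empty
#'   set yields 0.
#' @return A [bigint] with the exact count (use `format()` for the digits,
#'   `as.numeric()` for an approximation).
#' @export
count_search_space <- function(space = unet_space(), depths = space$depths) {
  depths <- unique(as.integer(depths))
  if (length(depths) > 0 && any(depths < 1L | depths > 5L))
    stop("depths must lie in 1..5")
  b <- bigint(count_block_configs(space))
  total <- bigint(0)
  for (d in depths) total <- big_add(total, big_pow(b, 2L * d))
  total
}

#' Sample a uniform random genotype
#'
#' Depth is uniform over `depth_choices`; every block field is uniform over
#' its candidate set, with the SE ratio drawn only when the SE block is
#' enabled.  Uses R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param space A `unet_space`.
#' @param depth_choices Depths to sample from (default `space$depths`).
#' @return A valid `unet_genotype`.
#' @export
sample_genotype <- function(space = unet_space(), depth_choices = space$depths) {
  depth_choices <- as.integer(depth_choices)
  if (length(depth_choices) == 0) stop("depth_choices must be nonempty")
  if (any(!(depth_choices %in% space$depths)))
    stop("depth_choices outside the space")
  d <- sample_one(depth_choices)
  blocks <- function() {
    lapply(seq_len(d), function(i) {
      se <- space$se_allowed && sample_one(c(TRUE, FALSE))
      block_config(sample_one(space$patterns), sample_one(space$filters),
                   se = se,
                   se_ratio = if (se) sample_one(space$se_ratios) else NULL)
    })
  }
  genotype(blocks(), blocks())
}

# sample() treats a length-1 numeric as 1:n; this does not
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Serialize a genotype to a plain list / restore it
#'
#' The record form is JSON-ready: connection patterns appear as 4-character
#' bitstrings (`"1110"`), SE ratios are `NULL` when the SE block is off.
#' `record_to_genotype` validates while parsing and names the offending
#' field on malformed input.
#'
#' @param g A `unet_genotype`.
#' @param record A list as produced by `genotype_to_record` (e.g. parsed
#'   from JSON).
#' @return `genotype_to_record`: a list; `record_to_genotype`: a
#'   `unet_genotype`.
#' @export
genotype_to_record <- function(g) {
  validate_genotype(g)
  side <- function(blocks) {
    lapply(blocks, function(b) {
      list(pattern = pattern_to_bits(b$pattern), filters = b$filters,
           se = b$se, se_ratio = if (b$se) b$se_ratio else NULL)
    })
  }
  list(depth = g$depth, encoders = side(g$encoders), decoders = side(g$decoders))
}

#' @rdname genotype_to_record
#' @export
record_to_genotype <- function(record) {
  need <- function(x, field, where) {
    if (is.null(x)) stop("malformed genotype record: missing `", field,
                         "` in ", where)
    x
  }
  depth <- need(record$depth, "depth", "record")
  side <- function(blocks, nm) {
    if (length(blocks) != depth)
      stop("malformed genotype record: `", nm, "` has ", length(blocks),
           " blocks but depth is ", depth)
    lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      where <- sprintf("%s[%d]", nm, i)
      pat <- need(b$pattern, "pattern", where)
      filt <- need(b$filters, "filters", where)
      se <- isTRUE(need(b$se, "se", where))
      block_config(pat, filt, se = se,
                   se_ratio = if (se) need(b$se_ratio, "se_ratio", where))
    })
  }
  genotype(side(record$encoders, "encoders"), side(record$decoders, "decoders"))
}

#' Read/write genotypes as JSON
#' @param g A `unet_genotype`.
#' @param path File path.
#' @return `read_genotype` returns a `unet_genotype`; `write_genotype`
#'   returns `path` invisibly.
#' @export
write_genotype <- function(g, path) {
  jsonlite::write_json(genotype_to_record(g), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_genotype
#' @export
read_genotype <- function(path) {
  record_to_genotype(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Reference genotypes
#'
#' `searched_genotype()` loads the depth-5 architecture found by the
#' full-scale tuned search, shipped as a JSON fixture; it is the default
#' subject of the sensitivity protocols.  `baseline_genotype()` builds a
#' plain handcrafted comparison architecture: an Inception-flavoured U-Net
#' with all four branches active in every block and no SE recalibration.
#' It is a documented synthetic stand-in for the handcrafted network used
#' as the comparison anchor, not a reproduction of any published model.
#'
#' @param depth Baseline depth (default 5).
#' @param filters Baseline filter count used in every block.
#' @return A `unet_genotype`.
#' @export
searched_genotype <- function() {
  read_genotype(system.file("extdata", "searched_genotype.json",
                            package = "robunet", mustWork = TRUE))
}

#' @rdname searched_genotype
#' @export
baseline_genotype <- function(depth = 5L, filters = 32L) {
  blocks <- lapply(seq_len(depth), function(i) block_config(15L, filters))
  genotype(blocks, lapply(seq_len(depth), function(i) block_config(15L, filters)))
}
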