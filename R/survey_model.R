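# Domain types and CSV I/O for use/availability tick surveys.

#' Life stages, seasons and collection methods recognised by the package
#'
#' Capture counts are indexed by life stage (larva, nymph, female, male),
#' season (dry, wet) and collection method (CO2 trap, cloth-drag transect).
#' These vectors define the canonical levels and their order.
#'
#' @name survey-levels
#' @keywords internal
NULL

tick_stages  <- c("larva", "nymph", "female", "male")
tick_seasons <- c("dry", "wet")
tick_methods <- c("trap", "transect")

#' Construct a habitat set
#'
#' A habitat set is the ordered collection of discrete habitats in the study
#' area together with the potentially available area of each, in square
#' metres. Habitat order is the input order and is preserved in every
#' downstream vector; all reports index habitats by name.
#'
#' @param names character vector of unique habitat labels (length >= 2).
#' @param areas numeric vector of strictly positive available areas (m^2),
#'   same length as `names`.
#' @return An object of class `habitat_set`: a list with elements `names`,
#'   `areas` (named numeric) and `k` (number of habitats).
#' @examples
#' habitat_set(c("Forest", "Paddock"), c(450552, 54968))
#' @export
habitat_set <- function(names, areas) {
  names <- as.character(names)
  areas <- as.numeric(areas)
  if (length(names) != length(areas))
    stop("`names` and `areas` must have the same length")
  if (length(names) < 2)
    stop("a habitat set needs at least 2 habitats")
  if (anyDuplicated(names))
    stop("duplicate habitat name: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (anyNA(areas))
    stop("non-numeric habitat area")
  if (any(areas <= 0))
    stop("habitat areas must be strictly positive")
  structure(
    list(names = names, areas = stats::setNames(areas, names),
         k = length(names)),
    class = "habitat_set")
}

#' @export
print.habitat_set <- function(x, ...) {
  cat("Habitat set:", x$k, "habitats,",
      format(sum(x$areas), big.mark = ","), "m^2 total\n")
  print(x$areas)
  invisible(x)
}

#' Read a habitat availability table from CSV
#'
#' Expects a header `habitat,area_m2` and at least two rows. Row order in
#' the file becomes the canonical habitat order.
#'
#' @param path path to a CSV file.
#' @return A [habitat_set()].
#' @export
load_habitats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("habitat", "area_m2") %in% names(df)))
    stop("expected header `habitat,area_m2` in ", path)
  areas <- suppressWarnings(as.numeric(df$area_m2))
  if (anyNA(areas))
    stop("non-numeric area in ", path, " (row ",
         which(is.na(areas))[1] + 1L, ")")
  habitat_set(df$habitat, areas)
}

#' Write a habitat set to CSV
#'
#' @param habitats a [habitat_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_habitats <- function(habitats, path) {
  stopifnot(inherits(habitats, "habitat_set"))
  utils::write.csv(
    data.frame(habitat = habitats$names,
               area_m2 = unname(habitats$areas)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a capture-count matrix
#'
#' Counts are stored as a 4-way integer array indexed by
#' `[stage, habitat, season, method]`. Missing combinations default to zero:
#' real surveys legitimately contain structural zeros (immature stages can be
#' absent from whole habitats in the wet season).
#'
#' @param df a data.frame with columns `group, habitat, season, method,
#'   count` (`group` in larva/nymph/female/male; `season` dry/wet; `method`
#'   trap/transect). May be empty.
#' @param habitats the associated [habitat_set()]; every habitat in `df`
#'   must belong to it.
#' @return An object of class `count_matrix`: the 4-way array with a
#'   `habitats` attribute.
#' @export
count_matrix <- function(df, habitats) {
  stopifnot(inherits(habitats, "habitat_set"))
  arr <- array(0L,
               dim = c(length(tick_stages), habitats$k,
                       length(tick_seasons), length(tick_methods)),
               dimnames = list(stage = tick_stages, habitat = habitats$names,
                               season = tick_seasons, method = tick_methods))
  if (nrow(df) > 0) {
    need <- c("group", "habitat", "season", "method", "count")
    if (!all(need %in% names(df)))
      stop("count table needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(df$group), tick_stages)
    if (length(bad)) stop("unknown group token: ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$habitat), habitats$names)
    if (length(bad)) stop("unknown habitat: ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$season), tick_seasons)
    if (length(bad)) stop("unknown season token: ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$method), tick_methods)
    if (length(bad)) stop("unknown method token: ", paste(bad, collapse = ", "))
    cnt <- suppressWarnings(as.numeric(df$count))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
      stop("counts must be non-negative integers (row ",
           which(is.na(cnt) | cnt < 0 | cnt != floor(cnt))[1], ")")
    for (i in seq_len(nrow(df)))
      arr[df$group[i], df$habitat[i], df$season[i], df$method[i]] <-
        arr[df$group[i], df$habitat[i], df$season[i], df$method[i]] +
        as.integer(cnt[i])
  }
  structure(arr, habitats = habitats, class = "count_matrix")
}

#' Read a capture-count table from CSV
#'
#' Expects a header `group,habitat,season,method,count`. Combinations absent
#' from the file are zero.
#'
#' @inheritParams count_matrix
#' @param path path to a CSV file.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, habitats) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  count_matrix(df, habitats)
}

#' Write a count matrix to the standard CSV dialect
#'
#' Zero cells are omitted; `load_counts()` restores them, so write-then-load
#' round-trips exactly.
#'
#' @param counts a [count_matrix()].
#' @param path output path.
#' @param keep_zeros write all cells including zeros.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, keep_zeros = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  long <- as.data.frame.table(unclass(counts), responseName = "count",
                              stringsAsFactors = FALSE)
  names(long) <- c("group", "habitat", "season", "method", "count")
  if (!keep_zeros) long <- long[long$count > 0, , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Habitats associated with a count matrix
#' @param counts a [count_matrix()].
#' @return The [habitat_set()] the counts are indexed by.
#' @export
habitats_of <- function(counts) attr(counts, "habitats")

# Resolve a group selector to the stage rows it pools.
resolve_group <- function(group) {
  g <- match.arg(tolower(group),
                 c(tick_stages, "larvae", "nymphs", "females", "males",
                   "adults", "all"))
  switch(g,
         larvae = "larva", nymphs = "nymph", females = "female",
         males = "male", adults = c("female", "male"),
         all = tick_stages, g)
}

#' Observed-use profile for one group and season
#'
#' Pools both collection methods (inference is done on pooled counts; methods
#' matter only for composition summaries) and the selected stages, yielding
#' the per-habitat observed counts `O`, their total `N`, and the use
#' proportions `r = O/N`.
#'
#' @param counts a [count_matrix()].
#' @param group one of `"larva"`, `"nymph"`, `"female"`, `"male"`,
#'   `"adults"` (female + male) or `"all"` (every stage). Plural stage names
#'   are accepted.
#' @param season `"dry"` or `"wet"`.
#' @return An object of class `use_profile`: list with `group`, `season`,
#'   `O` (named counts), `N`, `r` (named proportions).
#' @examples
#' hs <- habitat_set(c("A", "B"), c(100, 300))
#' cm <- count_matrix(data.frame(group = "nymph", habitat = c("A", "B"),
#'                               season = "dry", method = "trap",
#'                               count = c(30, 10)), hs)
#' use_profile(cm, "nymph", "dry")$r
#' @export
use_profile <- function(counts, group, season) {
  stopifnot(inherits(counts, "count_matrix"))
  season <- match.arg(season, tick_seasons)
  stages <- resolve_group(group)
  sub <- unclass(counts)[stages, , season, , drop = FALSE]
  O <- apply(sub, 2, sum)
  N <- sum(O)
  if (N == 0)
    stop("empty profile: no captures for group `", group,
         "` in the ", season, " season")
  structure(list(group = group, season = season,
                 O = O, N = N, r = O / N),
            class = "use_profile")
}

#' @export
print.use_profile <- function(x, ...) {
  cat("Use profile:", x$group, "/", x$season, " (N =", x$N, ")\n")
  print(rbind(O = x$O, r = round(x$r, 4)))
  invisible(x)
}
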