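#' Read a Stacks-style population map
#'
#' Two tab-separated columns (sample, population); lines starting with `#`
#' are comments.
#'
#' @param path Path to the popmap file.
#' @return Tibble with columns `sample`, `pop`.
#' @export
read_popmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("popmap '", path, "': line ", which(lengths(parts) < 2)[1],
         " does not have two tab-separated columns")
  }
  pm <- tibble::tibble(sample = vapply(parts, `[`, "", 1),
                       pop = vapply(parts, `[`, "", 2))
  dup <- pm |>
    dplyr::distinct(.data$sample, .data$pop) |>
    dplyr::count(.data$sample) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("popmap '", path, "': sample(s) mapped to more than one population: ",
         paste(dup$sample, collapse = ", "))
  }
  dplyr::distinct(pm)
}

#' Write a population map
#' @param pm Tibble with columns `sample`, `pop`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  writeLines(paste(pm$sample, pm$pop, sep = "\t"), path)
  invisible(path)
}

#' Define a group partition over populations
#'
#' Maps population labels to `k >= 2` named groups (e.g. East-Honshu /
#' West-Honshu / Kyushu analogues), the unit at which fixation indices,
#' ancestry fractions and diagnostic markers are computed.
#'
#' @param pop Character vector of population labels.
#' @param group Character vector of group names, same length.
#' @return Tibble with columns `pop`, `group`; class `group_partition`.
#' @export
group_partition <- function(pop, group) {
  part <- tibble::tibble(pop = as.character(pop), group = as.character(group))
  if (anyDuplicated(part$pop)) stop("each population maps to one group")
  if (length(unique(part$group)) < 2) stop("a partition needs k >= 2 groups")
  class(part) <- c("group_partition", class(part))
  part
}

#' Read a two-column partition file (pop TAB group)
#' @param path Path to a tab-separated file, `#` comments allowed.
#' @return A [group_partition].
#' @export
read_partition <- function(path) {
  pm <- read_popmap(path)
  group_partition(pm$sample, pm$pop)
}

#' Group membership per sample
#'
#' @param pm Popmap tibble (`sample`, `pop`).
#' @param partition A [group_partition].
#' @return Named character vector sample -> group (`NA` for populations not
#'   covered by the partition).
#' @export
sample_groups <- function(pm, partition) {
  g <- partition$group[match(pm$pop, partition$pop)]
  stats::setNames(g, pm$sample)
}

# sample ids of one group, in gm order
group_samples <- function(gm, pm, partition, grp) {
  sg <- sample_groups(pm, partition)
  gm$samples[gm$samples %in% names(sg)[!is.na(sg) & sg == grp]]
}

# merge a partition into two groups: `merge` groups become `into`
collapse_partition <- function(partition, merge, into) {
  group_partition(partition$pop,
                  ifelse(partition$group %in% merge, into, partition$group))
}
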