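GUILDS <- c("high_profile", "low_profile", "motile", "planktonic")

#' Genus-to-guild lookup tables
#'
#' Benthic diatoms fall into four ecological guilds reflecting attachment
#' and motility: high profile (attached, turbulence-exposed), low profile
#' (firmly attached, turbulence-resistant), motile (loosely attached,
#' moving in the biofilm) and planktonic (free floating). Guild can be
#' assigned from genus, refined by an optional maximum cell size (µm):
#' size-bounded rules take precedence over genus-general ones. The shipped
#' default table covers the genera typical of sea-turtle biofilms and is
#' configuration, not ground truth — edit it for other systems.
#'
#' @param path CSV with columns `genus`, `max_size_um` (blank for no
#'   bound), `guild`. Default: the table shipped with the package.
#' @return a `guild_lookup` data.frame.
#' @export
read_guild_lookup <- function(path = system.file("extdata",
                                                 "guild_lookup.csv",
                                                 package = "epidiatom")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genus", "max_size_um", "guild")
  if (!all(need %in% names(df)))
    stop("guild lookup must have columns: ", paste(need, collapse = ", "))
  df$max_size_um <- suppressWarnings(as.numeric(df$max_size_um))
  bad <- !df$guild %in% GUILDS
  if (any(bad))
    stop("unknown guild '", df$guild[bad][1L], "' (allowed: ",
         paste(GUILDS, collapse = ", "), ")")
  key <- paste(df$genus, ifelse(is.na(df$max_size_um), "", df$max_size_um))
  if (anyDuplicated(key))
    stop("conflicting duplicate rule for genus '",
         df$genus[duplicated(key)][1L], "'")
  structure(df, class = c("guild_lookup", "data.frame"))
}

#' Extract the genus from a taxon name
#'
#' Drops qualifiers (`cf.`, `aff.`) and returns the first name token.
#' @param taxon taxon name(s).
#' @return character vector of genera.
#' @export
genus_of <- function(taxon) {
  taxon <- sub("^(cf\\.|aff\\.)\\s*", "", trimws(taxon), ignore.case = TRUE)
  vapply(strsplit(taxon, "\\s+"), `[[`, character(1L), 1L)
}

#' Assign an ecological guild to a taxon
#'
#' Applies the lookup with stated precedence: among rules for the taxon's
#' genus, a size-bounded rule matches when a size is given and
#' `size <= max_size_um` (smallest bound first); otherwise the genus-general
#' rule applies; otherwise the taxon is `unclassified`.
#'
#' @param taxon taxon name (genus extracted from the first word).
#' @param size optional cell size in µm.
#' @param lookup a [read_guild_lookup()] table.
#' @return guild name or `"unclassified"`.
#' @export
assign_guild <- function(taxon, size = NULL, lookup = read_guild_lookup()) {
  stopifnot(inherits(lookup, "guild_lookup"))
  g <- genus_of(taxon)
  rules <- lookup[lookup$genus == g, , drop = FALSE]
  if (nrow(rules) == 0L) return("unclassified")
  sized <- rules[!is.na(rules$max_size_um), , drop = FALSE]
  if (!is.null(size) && nrow(sized)) {
    sized <- sized[order(sized$max_size_um), , drop = FALSE]
    hit <- which(size <= sized$max_size_um)
    if (length(hit)) return(sized$guild[hit[1L]])
  }
  general <- rules[is.na(rules$max_size_um), , drop = FALSE]
  if (nrow(general)) general$guild[1L] else "unclassified"
}

#' Per-sample ecological guild profile
#'
#' Aggregates a sample-by-taxon table into percentages of total abundance
#' per guild, with unclassified mass reported as a fifth column rather than
#' redistributed; the five percentages sum to 100 per sample.
#'
#' @param t an [abundance_table()].
#' @param assignments named character vector taxon -> guild (from
#'   [assign_guild()]); every taxon must be covered (use `"unclassified"`).
#' @return a `guild_profile`: percent-mode [abundance_table()] with columns
#'   `high_profile`, `low_profile`, `motile`, `planktonic`, `unclassified`.
#' @export
guild_profile <- function(t, assignments) {
  stopifnot(inherits(t, "abundance_table"))
  missing <- setdiff(colnames(t), names(assignments))
  if (length(missing))
    stop("taxa without a guild assignment: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  lv <- c(GUILDS, "unclassified")
  a <- assignments[colnames(t)]
  if (any(!a %in% lv)) stop("unknown guild label: ", a[!a %in% lv][1L])
  # percent tables are aggregated at input precision (printed tables may
  # carry rounding, e.g. rows summing to 100.1); counts are normalized
  rel <- if (table_mode(t) == "count") to_relative_abundance(t) else t
  out <- sapply(lv, function(g)
    rowSums(unclass(rel)[, a == g, drop = FALSE]))
  out <- matrix(out, nrow = nrow(t),
                dimnames = list(rownames(t), lv))
  tab <- abundance_table(out, rownames(t), lv, mode = "percent")
  class(tab) <- c("guild_profile", class(tab))
  tab
}

#' Samples with the extreme abundance of a guild
#'
#' @param p a [guild_profile()] (or any percent table with guild columns).
#' @param guild one of `high_profile`, `low_profile`, `motile`,
#'   `planktonic`, `unclassified`.
#' @return list with `min = list(sample, value)` and
#'   `max = list(sample, value)`; ties broken by first sample in row order.
#' @export
guild_extremes <- function(p, guild) {
  stopifnot(inherits(p, "abundance_table"))
  if (!guild %in% colnames(p))
    stop("unknown guild '", guild, "'")
  v <- unclass(p)[, guild]
  list(min = list(sample = rownames(p)[which.min(v)], value = unname(min(v))),
       max = list(sample = rownames(p)[which.max(v)], value = unname(max(v))))
}
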