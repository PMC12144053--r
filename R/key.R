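#' Social-media category schemes
#'
#' The four categorization schemes under which an app can count as social
#' media: research-coded narrow social networking (`sns`), research-coded
#' broad social media (`broad`), Play-Store-assigned (`google_play`), and
#' the survey-defined popular apps (`popular`).
#' @export
SM_CATEGORIES <- c("sns", "broad", "google_play", "popular")

#' Load a social-media app category key
#'
#' Reads a delimited key file mapping Android package names to membership
#' flags under the four categorization schemes. The expected dialect is
#' UTF-8 CSV with header `app_label,package_name,sns,broad,google_play,
#' popular` and `1`/`0` flags; lines starting with `#` (e.g. a schema-version
#' note) are ignored.
#'
#' Structural invariants are enforced on load: package names must be unique,
#' every `sns` app must also be `broad` (the narrow scheme is a subset of the
#' broad one by construction), and every `popular` app must be `broad`.
#' Play-Store membership is independent of the research-coded schemes.
#'
#' @param path path to the key file. The default is the packaged reference
#'   key of 44 apps observed in a one-month adolescent pilot cohort.
#' @return a data.frame of class `sm_key` with columns `app_label`,
#'   `package_name`, and logical `sns`, `broad`, `google_play`, `popular`.
#' @export
#' @examples
#' key <- load_key()
#' nrow(key)                     # 44 apps
#' length(category_members(key, "broad"))
load_key <- function(path = system.file("extdata", "social_media_key.csv",
                                        package = "smsense")) {
  if (!file.exists(path)) stop("key file not found: ", path, call. = FALSE)
  key <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer",
                                        "integer", "integer", "integer"))
  expected <- c("app_label", "package_name", "sns", "broad", "google_play",
                "popular")
  if (!identical(names(key), expected)) {
    stop("key header must be ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  for (col in SM_CATEGORIES) {
    bad <- !(key[[col]] %in% c(0L, 1L))
    if (any(bad)) {
      stop("non-binary flag in column '", col, "' at row ", which(bad)[1L],
           call. = FALSE)
    }
    key[[col]] <- as.logical(key[[col]])
  }
  dup <- unique(key$package_name[duplicated(key$package_name)])
  if (length(dup)) {
    stop("duplicate package names in key: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  viol <- key$package_name[key$sns & !key$broad]
  if (length(viol)) {
    stop("sns apps missing the broad flag: ", paste(viol, collapse = ", "),
         call. = FALSE)
  }
  viol <- key$package_name[key$popular & !key$broad]
  if (length(viol)) {
    stop("popular apps missing the broad flag: ",
         paste(viol, collapse = ", "), call. = FALSE)
  }
  class(key) <- c("sm_key", "data.frame")
  key
}

.check_key <- function(key) {
  if (!inherits(key, "sm_key")) stop("`key` must come from load_key()",
                                     call. = FALSE)
  invisible(key)
}

.check_category <- function(category) {
  if (!is.character(category) || length(category) != 1L ||
      !(category %in% SM_CATEGORIES)) {
    stop("unknown category: ", deparse(category), "; must be one of ",
         paste(SM_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  category
}

#' Look up the social-media categories of a package
#'
#' Pure, exact, case-sensitive lookup (Android package ids are canonical).
#' A package absent from the key is simply not social media under any
#' scheme and returns an empty vector.
#'
#' @param package_name character vector of Android package names.
#' @param key an `sm_key` from [load_key()].
#' @return for a single package, a character vector (subset of
#'   [SM_CATEGORIES]); for several, a named list of such vectors.
#' @export
#' @examples
#' categorize("com.snapchat.android", load_key())
categorize <- function(package_name, key = load_key()) {
  .check_key(key)
  one <- function(p) {
    i <- match(p, key$package_name)
    if (is.na(i)) return(character())
    SM_CATEGORIES[c(key$sns[i], key$broad[i], key$google_play[i],
                    key$popular[i])]
  }
  if (length(package_name) == 1L) return(one(package_name))
  stats::setNames(lapply(package_name, one), package_name)
}

#' Member packages of a category scheme
#'
#' @param key an `sm_key` from [load_key()].
#' @param category one of `"sns"`, `"broad"`, `"google_play"`, `"popular"`.
#' @return character vector of package names.
#' @export
category_members <- function(key, category) {
  .check_key(key)
  .check_category(category)
  key$package_name[key[[category]]]
}

#' Validate a category key file
#'
#' Parses a key file, reports member counts per scheme and any invariant
#' violations (duplicate packages, narrow-not-in-broad, popular-not-in-broad,
#' non-binary flags). Unlike [load_key()] this never throws on invariant
#' violations; it reports them, for key maintenance as app catalogs evolve.
#'
#' @param path key file path.
#' @return list with `counts` (named integer vector per scheme plus `n_apps`)
#'   and `violations` (character vector, empty when clean), classed
#'   `sm_key_report`.
#' @export
validate_key <- function(path = system.file("extdata",
                                            "social_media_key.csv",
                                            package = "smsense")) {
  violations <- character()
  key <- tryCatch(load_key(path), error = function(e) {
    violations <<- conditionMessage(e)
    NULL
  })
  if (is.null(key)) {
    # reparse leniently to still report counts where possible
    raw <- tryCatch(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE),
                    error = function(e) NULL)
    counts <- c(n_apps = if (is.null(raw)) NA_integer_ else nrow(raw),
                stats::setNames(rep(NA_integer_, 4L), SM_CATEGORIES))
    if (!is.null(raw)) {
      for (col in intersect(SM_CATEGORIES, names(raw))) {
        counts[col] <- sum(raw[[col]] %in% c(1L, "1", TRUE), na.rm = TRUE)
      }
    }
  } else {
    counts <- c(n_apps = nrow(key),
                vapply(SM_CATEGORIES, function(cl) sum(key[[cl]]),
                       integer(1)))
  }
  structure(list(counts = counts, violations = violations,
                 path = path, clean = length(violations) == 0L),
            class = "sm_key_report")
}

#' @export
print.sm_key_report <- function(x, ...) {
  cat("Social-media key:", x$path, "\n")
  cat(sprintf("  apps: %s | sns: %s | broad: %s | google_play: %s | popular: %s\n",
              x$counts["n_apps"], x$counts["sns"], x$counts["broad"],
              x$counts["google_play"], x$counts["popular"]))
  if (x$clean) cat("  invariants: OK\n")
  else cat("  violations:\n", paste0("   - ", x$violations, "\n"))
  invisible(x)
}
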