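#' Menu catalog for an on-demand SMS service
#'
#' The catalog describes the hierarchical menu a subscriber navigates by
#' texting numeric codes: a service keyword at the root, a main (welcome) menu,
#' topical submenus, content codes under each submenu, and an optional
#' ward-lookup node for clinic location queries (answered by texting the first
#' 3-4 letters of a ward name). Nodes carry an `active_from` date so that
#' menus introduced mid-deployment never match earlier queries.
#'
#' @param nodes a data frame with columns `code`, `label`,
#'   `level` (one of `"keyword"`, `"main"`, `"submenu"`, `"content"`,
#'   `"ward_lookup"`), `parent` (code of the parent node, `NA` for the
#'   keyword root) and `active_from` (`Date`; `NA` means always active).
#' @param keyword canonical service keyword (case-insensitive), e.g. `"m4rh"`.
#' @param misspellings character vector of recognized keyword misspellings.
#' @return an object of class `menu_catalog`.
#' @export
menu_catalog <- function(nodes, keyword, misspellings = character()) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("code", "label", "level", "parent", "active_from")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("catalog nodes missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  nodes$code <- tolower(as.character(nodes$code))
  nodes$parent <- tolower(as.character(nodes$parent))
  nodes$active_from <- as.Date(nodes$active_from)
  keyword <- tolower(keyword)
  misspellings <- tolower(misspellings)

  if (anyDuplicated(nodes$code)) {
    stop("catalog codes must be unique", call. = FALSE)
  }
  levels_ok <- c("keyword", "main", "submenu", "content", "ward_lookup")
  if (!all(nodes$level %in% levels_ok)) {
    stop("unknown node level(s): ",
         paste(setdiff(nodes$level, levels_ok), collapse = ", "), call. = FALSE)
  }
  root <- nodes$code[nodes$level == "keyword"]
  if (length(root) != 1 || root != keyword) {
    stop("catalog must contain exactly one keyword node whose code is the keyword",
         call. = FALSE)
  }
  non_root <- nodes[nodes$level != "keyword", ]
  if (any(is.na(non_root$parent)) || !all(non_root$parent %in% nodes$code)) {
    stop("every non-keyword node needs a parent present in the catalog", call. = FALSE)
  }
  # tree check: walking parents from every node must reach the keyword root
  parent_of <- setNames(nodes$parent, nodes$code)
  for (code in nodes$code) {
    seen <- character()
    cur <- code
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop("catalog parent links contain a cycle", call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
    if (cur != root) stop("node '", code, "' does not descend from the keyword root",
                          call. = FALSE)
  }
  content_parents <- nodes$level[match(nodes$parent[nodes$level == "content"], nodes$code)]
  if (!all(content_parents == "submenu")) {
    stop("every content node's parent must be a submenu node", call. = FALSE)
  }

  structure(
    list(nodes = nodes, keyword = keyword, misspellings = misspellings),
    class = "menu_catalog"
  )
}

#' @export
print.menu_catalog <- function(x, ...) {
  cat("<menu_catalog> keyword '", x$keyword, "' (",
      length(x$misspellings), " known misspellings), ",
      nrow(x$nodes), " nodes: ",
      paste(sprintf("%s=%d", names(table(x$nodes$level)), table(x$nodes$level)),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

catalog_level <- function(catalog, codes) {
  catalog$nodes$level[match(tolower(codes), catalog$nodes$code)]
}

# codes of a given level active on `date` (NA active_from = always active)
catalog_codes <- function(catalog, levels, date = NULL) {
  nodes <- catalog$nodes[catalog$nodes$level %in% levels, ]
  if (!is.null(date)) {
    nodes <- nodes[is.na(nodes$active_from) | nodes$active_from <= as.Date(date), ]
  }
  nodes$code
}

#' Read a menu catalog from a YAML file
#'
#' The file has three top-level keys: `keyword`, `misspellings`, and `nodes`
#' (a list of maps with `code`, `label`, `level`, `parent`, and optional
#' `active_from` in `YYYY-MM-DD`). See
#' `system.file("extdata", "menu_catalog.yaml", package = "m4rhfunnel")` for
#' the bundled m4RH Tanzania catalog.
#'
#' @param path path to the YAML catalog.
#' @return a [menu_catalog].
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$keyword) || is.null(raw$nodes)) {
    stop("catalog file must define 'keyword' and 'nodes'", call. = FALSE)
  }
  nodes <- purrr::map_dfr(raw$nodes, function(n) {
    tibble::tibble(
      code = as.character(n$code),
      label = n$label %||% as.character(n$code),
      level = n$level,
      parent = as.character(n$parent %||% NA_character_),
      active_from = as.Date(n$active_from %||% NA_character_)
    )
  })
  # the keyword root is implicit in the file
  if (!tolower(raw$keyword) %in% tolower(nodes$code)) {
    nodes <- dplyr::bind_rows(
      tibble::tibble(code = tolower(raw$keyword), label = "Service keyword",
                     level = "keyword", parent = NA_character_,
                     active_from = as.Date(NA)),
      nodes
    )
  }
  menu_catalog(nodes, keyword = raw$keyword,
               misspellings = unlist(raw$misspellings) %||% character())
}

#' The bundled m4RH Tanzania menu catalog
#'
#' Keyword `m4rh` (misspellings `mr4h`, `m4hr`, `mrh4`, `mfrh`), five topical
#' submenus (about family planning, family planning methods, youth, role model
#' stories, clinic locations), nine contraceptive-method content codes, three
#' youth content codes, and a ward-lookup node under the clinic submenu. The
#' "about family planning" and "youth" menus carry `active_from = 2015-01-01`:
#' they were added to the Tanzanian service in 2015 and never match earlier
#' queries. Code 66 (pregnancy prevention / family planning methods) is the
#' documented production code; the remaining numeric codes are plausible
#' stand-ins, as the full production code book is not public.
#'
#' @return a [menu_catalog].
#' @export
m4rh_catalog <- function() {
  read_catalog(system.file("extdata", "menu_catalog.yaml",
                           package = "m4rhfunnel", mustWork = TRUE))
}
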