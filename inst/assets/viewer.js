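/* Minimal static tiled-map viewer: pans and zooms over the tile
 * pyramid, drops persistent markers whose coordinates are stored once
 * at the most detailed level and rescaled by powers of two per level,
 * and opens callout popups. Data comes from data/index.json. */
(function () {
  "use strict";
  var map = document.getElementById("pa-map");
  if (!map) return;

  function init(data) {
    if (!data.levels || !data.levels.length) return;
    var level = 0, maxLevel = data.levels.length - 1;
    var detail = maxLevel; /* marker anchors recorded at this level */
    var origin = { x: 0, y: 0 }, drag = null;

    function scalePoint(p, from, to) {
      var f = Math.pow(2, to - from);
      return { x: p[0] * f, y: p[1] * f };
    }

    function render() {
      map.innerHTML = "";
      var L = data.levels[level], te = data.tile_edge;
      for (var ty = 0; ty < L.n_tiles_y; ty++) {
        for (var tx = 0; tx < L.n_tiles_x; tx++) {
          var img = document.createElement("img");
          img.className = "pa-tile";
          img.src = "tiles/" + L.level + "/" + tx + "_" + ty + ".png";
          img.style.left = (origin.x + tx * te) + "px";
          img.style.top = (origin.y + ty * te) + "px";
          map.appendChild(img);
        }
      }
      (data.markers || []).forEach(function (mk) {
        var p = scalePoint(mk.anchor, detail, level);
        var el = document.createElement("div");
        el.className = "pa-marker";
        el.title = mk.name;
        el.style.left = (origin.x + p.x) + "px";
        el.style.top = (origin.y + p.y) + "px";
        el.addEventListener("click", function (ev) {
          openCallout(mk, origin.x + p.x, origin.y + p.y);
          ev.stopPropagation();
        });
        map.appendChild(el);
      });
    }

    function openCallout(mk, x, y) {
      closeCallout();
      var div = document.createElement("div");
      div.className = "pa-callout";
      div.innerHTML = mk.callout;
      div.style.left = (x + 10) + "px";
      div.style.top = (y + 10) + "px";
      map.appendChild(div);
    }
    function closeCallout() {
      var c = map.querySelector(".pa-callout");
      if (c) c.remove();
    }

    map.addEventListener("mousedown", function (e) {
      drag = { x: e.clientX - origin.x, y: e.clientY - origin.y };
    });
    window.addEventListener("mousemove", function (e) {
      if (!drag) return;
      origin.x = e.clientX - drag.x;
      origin.y = e.clientY - drag.y;
      render();
    });
    window.addEventListener("mouseup", function () { drag = null; });
    map.addEventListener("dblclick", function () {
      level = Math.min(maxLevel, level + 1);
      origin.x *= 2; origin.y *= 2;
      render();
    });
    map.addEventListener("wheel", function (e) {
      e.preventDefault();
      if (e.deltaY > 0 && level > 0) {
        level--; origin.x /= 2; origin.y /= 2;
      } else if (e.deltaY < 0 && level < maxLevel) {
        level++; origin.x *= 2; origin.y *= 2;
      }
      render();
    });
    map.addEventListener("click", closeCallout);

    var search = document.getElementById("pa-search");
    var results = document.getElementById("pa-results");
    if (search && results) {
      search.addEventListener("input", function () {
        var q = search.value.toLowerCase();
        results.innerHTML = "";
        if (!q) return;
        (data.search || [])
          .filter(function (en) { return en.text.indexOf(q) >= 0; })
          .sort(function (a, b) {
            var d = a.text.indexOf(q) - b.text.indexOf(q);
            return d !== 0 ? d : a.name.localeCompare(b.name);
          })
          .forEach(function (en) {
            var d = document.createElement("div");
            d.textContent = en.name;
            results.appendChild(d);
          });
      });
    }
    render();
  }

  fetch("data/index.json")
    .then(function (r) { return r.json(); })
    .then(init)
    .catch(function () { /* file:// without fetch support */ });
})();
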