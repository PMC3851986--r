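body { font-family: sans-serif; margin: 0.8em; color: #222; }
h1 { font-size: 1.3em; }
.pa-layout { display: flex; gap: 1em; }
.pa-map { flex: 1 1 auto; min-height: 540px; position: relative;
  overflow: hidden; background: #fafafa; border: 1px solid #ccc; }
.pa-map img.pa-tile { position: absolute; pointer-events: none; }
.pa-side { width: 300px; flex: 0 0 auto; }
.pa-panel h3 { margin: 0.6em 0 0.2em; font-size: 0.95em;
  border-bottom: 1px solid #ddd; }
.pa-panel-group { list-style: none; margin: 0.2em 0; padding-left: 0.6em;
  font-size: 0.9em; }
.pa-panel-entry { text-decoration: none; }
#pa-search { width: 100%; box-sizing: border-box; }
#pa-results { font-size: 0.85em; max-height: 10em; overflow: auto; }
.pa-marker { position: absolute; width: 12px; height: 12px;
  margin: -6px 0 0 -6px; border-radius: 50%; background: #d33;
  border: 2px solid #fff; box-shadow: 0 0 3px #0008; cursor: pointer; }
.pa-callout { position: absolute; background: #fff; border: 1px solid #999;
  border-radius: 4px; padding: 0.5em; max-width: 320px; font-size: 0.85em;
  box-shadow: 0 2px 8px #0003; z-index: 10; }
.pa-ann-section { margin: 0.3em 0; padding: 0.3em 0.5em; border-radius: 3px; }
.pa-ann-section h4 { margin: 0 0 0.2em; font-size: 0.9em; }
.pa-globe { text-decoration: none; }
.pa-comment { border-top: 1px dotted #bbb; margin-top: 0.5em;
  padding-top: 0.3em; }
.pa-eq { color: #666; }
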