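<div class="laylink-note">Cultures confirmed <span class="laylink-term" data-stage="1" title="The presence of bacteria, a type of germ, in the blood">bacteremia</span>. CXR: <span class="laylink-term" data-stage="4" title="[community]: A group of people. | [pneumonia]: An infection of the lungs, usually caused by viruses or bacteria.">community acquired pneumonia</span>.</div>
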